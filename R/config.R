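#' Bundle model parameters and geometry into a beamline configuration
#'
#' A beamline configuration carries everything needed to evaluate the H/D
#' model: the irradiation geometry, the transport parameters, the regime
#' apportionment, and either an energy calibration (general-purpose in-water
#' beamline, continuous in energy) or a measured isocenter H/D plus beam
#' energy (single-energy in-air ocular beamline). Variant consistency is
#' enforced: in-air configurations must use scalar apportionment and zero
#' attenuation coefficients; in-water configurations use the energy-dependent
#' apportionment and a calibration.
#'
#' @param name Configuration name.
#' @param geometry A [beam_geometry()].
#' @param transport A [transport_parameters()].
#' @param apportionment A [regime_apportionment()] (in-water) or
#'   [scalar_apportionment()] (in-air).
#' @param calibration An [energy_calibration()]; in-water only.
#' @param hd_iso Measured isocenter H/D (Sv/Gy); in-air only.
#' @param energy Beam energy (MeV); in-air only.
#' @return An object of class `beamline_config`.
#' @seealso [beamline_preset()], [load_config()]
#' @export
beamline_config <- function(name, geometry, transport, apportionment,
                            calibration = NULL, hd_iso = NULL, energy = NULL) {
  stop_unless(is.character(name) && length(name) == 1L, "`name` must be a string")
  stop_unless(inherits(geometry, "beam_geometry"), "`geometry` must be a beam_geometry")
  stop_unless(inherits(transport, "transport_parameters"),
              "`transport` must be a transport_parameters")
  in_air <- geometry$environment == "in_air"
  if (in_air) {
    stop_unless(inherits(apportionment, "scalar_apportionment"),
                "in_air configuration requires a scalar_apportionment")
    if (any(transport$alpha != 0)) {
      stop("invalid configuration: field `transport$alpha` must be all zero for an in_air beamline",
           call. = FALSE)
    }
    stop_unless(is_scalar_num(hd_iso) && hd_iso > 0,
                "in_air configuration requires `hd_iso` > 0 (Sv/Gy)")
    stop_unless(is_scalar_num(energy) && energy > 0,
                "in_air configuration requires `energy` > 0 (MeV)")
    if (!is.null(calibration)) {
      stop("invalid configuration: `calibration` is not used for an in_air beamline",
           call. = FALSE)
    }
  } else {
    stop_unless(inherits(apportionment, "regime_apportionment"),
                "in_water configuration requires a regime_apportionment")
    stop_unless(inherits(calibration, "energy_calibration"),
                "in_water configuration requires an energy_calibration")
    if (!is.null(hd_iso)) {
      stop("invalid configuration: `hd_iso` is only used for an in_air beamline (use `calibration`)",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, geometry = geometry, transport = transport,
         apportionment = apportionment, calibration = calibration,
         hd_iso = hd_iso, energy = energy),
    class = "beamline_config"
  )
}

#' @export
print.beamline_config <- function(x, ...) {
  cat("<beamline_config>", x$name, "\n")
  cat("  environment:", x$geometry$environment,
      sprintf(" (d_iso = %g cm, iso_depth = %g cm)\n",
              x$geometry$d_iso, x$geometry$iso_depth))
  if (x$geometry$environment == "in_air") {
    cat(sprintf("  measured (H/D)_iso = %.3g Sv/Gy at %g MeV\n", x$hd_iso, x$energy))
    cat(sprintf("  scalar fractions C1..C4 = %s\n",
                paste(signif(unlist(x$apportionment[c("C1", "C2", "C3", "C4")]), 3),
                      collapse = ", ")))
  } else {
    cat(sprintf("  (H/D)_E,iso = %.3g * E^%.3g * %.3g Sv/Gy (ref %g MeV)\n",
                x$calibration$alpha_E, x$calibration$p_E,
                x$calibration$hd_ref_iso, x$calibration$ref_energy))
  }
  cat(sprintf("  q = %g; alpha = %s cm^-1; sigma = %s cm\n",
              x$transport$q, paste(signif(x$transport$alpha, 3), collapse = "/"),
              paste(signif(x$transport$sigma, 3), collapse = "/")))
  invisible(x)
}

#' Load a beamline configuration from a JSON file
#'
#' Reads and validates a configuration document. Unknown keys are rejected,
#' every required field must be present, and the in-air / in-water variant
#' invariants are enforced (see [beamline_config()]).
#'
#' @param path Path to a JSON configuration file.
#' @return A [beamline_config()].
#' @seealso [write_config()], [beamline_preset()]
#' @export
load_config <- function(path) {
  stop_unless(file.exists(path), paste0("config file not found: ", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  config_from_list(doc)
}

config_from_list <- function(doc) {
  check_keys(doc, required = c("name", "geometry", "transport", "apportionment"),
             optional = c("calibration", "hd_iso_Sv_per_Gy", "energy_MeV"),
             where = "top level")
  check_keys(doc$geometry, required = c("d_iso_cm", "iso_depth_cm", "environment"),
             optional = character(), where = "geometry")
  geometry <- beam_geometry(doc$geometry$d_iso_cm, doc$geometry$iso_depth_cm,
                            doc$geometry$environment)
  check_keys(doc$transport, required = c("alpha_cm_inv", "sigma_cm", "q"),
             optional = character(), where = "transport")
  transport <- transport_parameters(doc$transport$alpha_cm_inv,
                                    doc$transport$sigma_cm, doc$transport$q)
  ap <- doc$apportionment
  stop_unless(!is.null(ap$type), "field `apportionment$type` is missing")
  if (identical(ap$type, "energy_dependent")) {
    check_keys(ap, required = c("type", "a1", "b1", "a2", "b2", "c2", "d2",
                                "a3", "a4", "b4", "c4"),
               optional = c("renormalize", "energy_range_MeV"),
               where = "apportionment")
    apportionment <- regime_apportionment(
      ap$a1, ap$b1, ap$a2, ap$b2, ap$c2, ap$d2, ap$a3, ap$a4, ap$b4, ap$c4,
      renormalize = ap$renormalize %||% TRUE,
      energy_range = ap$energy_range_MeV %||% c(100, 250))
  } else if (identical(ap$type, "scalar")) {
    check_keys(ap, required = c("type", "C1", "C2", "C3", "C4"),
               optional = "renormalize", where = "apportionment")
    apportionment <- scalar_apportionment(ap$C1, ap$C2, ap$C3, ap$C4,
                                          renormalize = ap$renormalize %||% TRUE)
  } else {
    stop("field `apportionment$type` must be \"energy_dependent\" or \"scalar\"",
         call. = FALSE)
  }
  calibration <- NULL
  if (!is.null(doc$calibration)) {
    check_keys(doc$calibration,
               required = c("alpha_E", "p_E", "hd_ref_iso_Sv_per_Gy", "ref_energy_MeV"),
               optional = character(), where = "calibration")
    calibration <- energy_calibration(doc$calibration$alpha_E, doc$calibration$p_E,
                                      doc$calibration$hd_ref_iso_Sv_per_Gy,
                                      doc$calibration$ref_energy_MeV)
  }
  beamline_config(doc$name, geometry, transport, apportionment,
                  calibration = calibration,
                  hd_iso = doc$hd_iso_Sv_per_Gy, energy = doc$energy_MeV)
}

check_keys <- function(x, required, optional, where) {
  stop_unless(is.list(x) || is.data.frame(x),
              paste0("config section `", where, "` must be an object"))
  unknown <- setdiff(names(x), c(required, optional))
  if (length(unknown)) {
    stop("unknown config field(s) in ", where, ": ",
         paste0("`", unknown, "`", collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("missing config field(s) in ", where, ": ",
         paste0("`", missing, "`", collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a beamline configuration to JSON
#'
#' Inverse of [load_config()]: the written file reloads to an identical
#' configuration.
#'
#' @param config A [beamline_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stop_unless(inherits(config, "beamline_config"), "`config` must be a beamline_config")
  app <- config$apportionment
  doc <- list(
    name = config$name,
    geometry = list(d_iso_cm = config$geometry$d_iso,
                    iso_depth_cm = config$geometry$iso_depth,
                    environment = config$geometry$environment),
    transport = list(alpha_cm_inv = config$transport$alpha,
                     sigma_cm = config$transport$sigma,
                     q = config$transport$q)
  )
  if (inherits(app, "scalar_apportionment")) {
    doc$apportionment <- list(type = "scalar", C1 = app$C1, C2 = app$C2,
                              C3 = app$C3, C4 = app$C4,
                              renormalize = app$renormalize)
    doc$hd_iso_Sv_per_Gy <- config$hd_iso
    doc$energy_MeV <- config$energy
  } else {
    doc$apportionment <- list(type = "energy_dependent",
                              a1 = app$a1, b1 = app$b1, a2 = app$a2, b2 = app$b2,
                              c2 = app$c2, d2 = app$d2, a3 = app$a3, a4 = app$a4,
                              b4 = app$b4, c4 = app$c4,
                              renormalize = app$renormalize,
                              energy_range_MeV = app$energy_range)
    doc$calibration <- list(alpha_E = config$calibration$alpha_E,
                            p_E = config$calibration$p_E,
                            hd_ref_iso_Sv_per_Gy = config$calibration$hd_ref_iso,
                            ref_energy_MeV = config$calibration$ref_energy)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Shipped beamline configurations
#'
#' Two configurations ship with the package:
#' \describe{
#'   \item{`general_purpose_100_250`}{A general-purpose passively scattered
#'     beamline with the isocenter at 22 cm depth in a water phantom,
#'     continuous in proton energy from 100 to 250 MeV (power-law
#'     calibration, energy-dependent apportionment, q = 1.13).}
#'   \item{`ocular_75MeV`}{A single-scattering ocular beamline evaluated in
#'     air at 75 MeV: measured isocenter H/D of 5.2e-5 Sv/Gy, scalar
#'     apportionment, zero attenuation, q = 1.5.}
#' }
#' The source-to-isocenter distances (230 cm and 100 cm respectively) are
#' configuration values, not published quantities.
#'
#' @param name Preset name.
#' @return A [beamline_config()].
#' @export
#' @examples
#' beamline_preset("ocular_75MeV")
beamline_preset <- function(name = c("general_purpose_100_250", "ocular_75MeV")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".json"), package = "neutrondose",
                      mustWork = TRUE)
  load_config(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
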