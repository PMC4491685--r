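#' Power-law energy calibration of isocenter H/D
#'
#' Builds the calibration that maps proton beam energy to the total neutron
#' equivalent dose per therapeutic absorbed dose (H/D) at isocenter,
#' \deqn{(H/D)_{E,iso} = \alpha_E \, E^{p_E} \, (H/D)_{ref,iso}.}
#' `hd_ref_iso` is the H/D at isocenter for a beam of the reference energy,
#' typically obtained as the quotient of closed-collimator neutron yield and
#' open-collimator absorbed-dose yield (see [hd_ref_iso_from_yields()]).
#'
#' Published parameter sets need not be self-consistent at the reference
#' energy (printed values are rounded); use [self_consistent_calibration()]
#' when exact `hd_iso(ref_energy) == hd_ref_iso` is wanted.
#'
#' @param alpha_E Scaling factor (dimensionless when `E` is in MeV). Must be
#'   positive.
#' @param p_E Power-law exponent (dimensionless).
#' @param hd_ref_iso H/D at isocenter at the reference energy (Sv/Gy), > 0.
#' @param ref_energy Reference proton beam energy (MeV), > 0. Default 100.
#' @return An object of class `energy_calibration`.
#' @seealso [hd_iso()], [hd_ref_iso_from_yields()]
#' @export
#' @examples
#' cal <- energy_calibration(8.0e-9, 4.1, 1.2e-4)
#' hd_iso(250, cal)
energy_calibration <- function(alpha_E, p_E, hd_ref_iso, ref_energy = 100) {
  stop_unless(is_scalar_num(alpha_E) && alpha_E > 0, "`alpha_E` must be a positive number")
  stop_unless(is_scalar_num(p_E), "`p_E` must be a number")
  stop_unless(is_scalar_num(hd_ref_iso) && hd_ref_iso > 0, "`hd_ref_iso` must be positive (Sv/Gy)")
  stop_unless(is_scalar_num(ref_energy) && ref_energy > 0, "`ref_energy` must be positive (MeV)")
  structure(
    list(alpha_E = alpha_E, p_E = p_E, hd_ref_iso = hd_ref_iso, ref_energy = ref_energy),
    class = "energy_calibration"
  )
}

#' @describeIn energy_calibration Calibration with `alpha_E` derived as
#'   `ref_energy^(-p_E)` so that `hd_iso(ref_energy) == hd_ref_iso` exactly.
#' @export
self_consistent_calibration <- function(p_E, hd_ref_iso, ref_energy = 100) {
  energy_calibration(ref_energy^(-p_E), p_E, hd_ref_iso, ref_energy)
}

#' Isocenter H/D from collimator-closed and collimator-open yields
#'
#' The reference isocenter H/D is the quotient of the neutron equivalent dose
#' per proton with the final collimator closed and the therapeutic absorbed
#' dose per proton with the collimator open.
#'
#' @param h_per_p_closed Neutron equivalent dose per proton, closed collimator
#'   (Sv/proton). Must be >= 0.
#' @param d_per_p_open Absorbed dose per proton at isocenter, open collimator
#'   (Gy/proton). Must be > 0.
#' @return H/D at isocenter (Sv/Gy).
#' @export
#' @examples
#' hd_ref_iso_from_yields(1.2e-16, 1.0e-12)
hd_ref_iso_from_yields <- function(h_per_p_closed, d_per_p_open) {
  stop_unless(is_scalar_num(h_per_p_closed) && h_per_p_closed >= 0,
              "`h_per_p_closed` must be a non-negative number (Sv/proton)")
  stop_unless(is_scalar_num(d_per_p_open) && d_per_p_open > 0,
              "`d_per_p_open` must be a positive number (Gy/proton)")
  h_per_p_closed / d_per_p_open
}

#' Energy-dependent apportionment of H/D among the four neutron regimes
#'
#' The fractions of the total H/D carried by the four neutron energy regimes
#' are smooth functions of the proton beam energy `E` (MeV):
#' intranuclear-cascade (direct) neutrons follow a straight line
#' `C1 = a1*E + b1`; evaporation neutrons a cumulative normal with a lower
#' bound `C2 = a2*cnorm(E, b2, c2) + d2`; epithermal (1/E) neutrons a constant
#' `C3 = a3`; thermal neutrons a quadratic `C4 = a4*E^2 + b4*E + c4`. The four
#' fractions are constrained to sum to unity; with `renormalize = TRUE`
#' (the default) each fraction is divided by the raw sum at every energy so
#' the constraint holds exactly even for rounded published coefficients.
#'
#' @param a1 Slope of the cascade fraction (MeV^-1).
#' @param b1 Intercept of the cascade fraction (dimensionless).
#' @param a2 Scale of the evaporation cumulative normal (dimensionless).
#' @param b2 Mean of the cumulative normal (MeV).
#' @param c2 Width of the cumulative normal (MeV), > 0.
#' @param d2 Lower bound of the evaporation fraction (dimensionless). May be
#'   (numerically) negative as published; raw negative `C2` values are clipped
#'   at zero with a warning.
#' @param a3 Constant epithermal fraction (dimensionless).
#' @param a4,b4,c4 Quadratic, linear and constant coefficients of the thermal
#'   fraction (MeV^-2, MeV^-1, dimensionless).
#' @param renormalize Enforce the sum-to-unity constraint exactly at every
#'   energy. Default `TRUE`; always forced on during fitting.
#' @param energy_range Supported proton energy range (MeV); evaluation outside
#'   it warns. Default `c(100, 250)`.
#' @return An object of class `regime_apportionment`.
#' @seealso [regime_fractions()], [scalar_apportionment()]
#' @export
regime_apportionment <- function(a1, b1, a2, b2, c2, d2, a3, a4, b4, c4,
                                 renormalize = TRUE,
                                 energy_range = c(100, 250)) {
  for (nm in c("a1", "b1", "a2", "b2", "c2", "d2", "a3", "a4", "b4", "c4")) {
    stop_unless(is_scalar_num(get(nm)), sprintf("`%s` must be a number", nm))
  }
  stop_unless(c2 > 0, "`c2` (cumulative-normal width) must be positive")
  stop_unless(is.logical(renormalize) && length(renormalize) == 1L,
              "`renormalize` must be TRUE or FALSE")
  stop_unless(is.numeric(energy_range) && length(energy_range) == 2L &&
                energy_range[1] < energy_range[2],
              "`energy_range` must be an increasing pair of energies (MeV)")
  structure(
    list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, c2 = c2, d2 = d2, a3 = a3,
         a4 = a4, b4 = b4, c4 = c4, renormalize = renormalize,
         energy_range = energy_range),
    class = "regime_apportionment"
  )
}

#' Scalar apportionment for a single-energy beamline
#'
#' The in-air ocular variant of the model replaces the energy-dependent
#' regime fractions with four scalar coefficients.
#'
#' @param C1,C2,C3,C4 Fractions of H/D carried by the cascade, evaporation,
#'   epithermal and thermal regimes. Each must be >= 0.
#' @param renormalize Enforce sum-to-unity exactly. Default `TRUE`.
#' @return An object of class `scalar_apportionment`.
#' @export
#' @examples
#' scalar_apportionment(1.1e-2, 7.8e-1, 1.0e-1, 9.6e-2)
scalar_apportionment <- function(C1, C2, C3, C4, renormalize = TRUE) {
  C <- c(C1, C2, C3, C4)
  stop_unless(is.numeric(C) && length(C) == 4L && all(is.finite(C)),
              "`C1`..`C4` must be numbers")
  if (any(C < 0)) {
    bad <- regime_names()[which(C < 0)[1]]
    stop("invalid parameter: scalar fraction for the ", bad,
         " regime is negative", call. = FALSE)
  }
  stop_unless(sum(C) > 0, "scalar fractions must not all be zero")
  structure(
    list(C1 = C1, C2 = C2, C3 = C3, C4 = C4, renormalize = renormalize),
    class = "scalar_apportionment"
  )
}

#' Neutron transport parameters: attenuation, lateral width, distance falloff
#'
#' Per-regime water attenuation coefficients `alpha` (cm^-1, the reciprocal
#' neutron mean free paths), Gaussian lateral width parameters `sigma` (cm),
#' and the exponent `q` of the power-law falloff of H/D with distance from
#' the effective neutron source.
#'
#' @param alpha Numeric length-4: attenuation coefficients for the cascade,
#'   evaporation, epithermal and thermal regimes (cm^-1). All >= 0; exactly 0
#'   for the in-air variant.
#' @param sigma Numeric length-4: lateral Gaussian widths (cm), all > 0.
#' @param q Distance falloff exponent (dimensionless), > 0.
#' @return An object of class `transport_parameters`.
#' @export
#' @examples
#' transport_parameters(alpha = c(1.3e-2, 1.3e-2, 3.2e-2, 3.3e-1),
#'                      sigma = c(14, 77, 3900, 3900), q = 1.13)
transport_parameters <- function(alpha, sigma, q) {
  stop_unless(is.numeric(alpha) && length(alpha) == 4L && all(alpha >= 0),
              "`alpha` must be four non-negative attenuation coefficients (cm^-1)")
  stop_unless(is.numeric(sigma) && length(sigma) == 4L && all(sigma > 0),
              "`sigma` must be four positive Gaussian widths (cm)")
  stop_unless(is_scalar_num(q) && q > 0, "`q` must be a positive falloff exponent")
  structure(
    list(alpha = unname(alpha), sigma = unname(sigma), q = q),
    class = "transport_parameters"
  )
}

#' Beamline irradiation geometry
#'
#' Positions the effective neutron source (at the final collimator /
#' treatment-head exit), the isocenter, and the water phantom. Coordinates
#' are Cartesian with origin at the effective source and +z along the beam
#' axis; the phantom entrance plane sits at axial distance
#' `d_iso - iso_depth` from the source.
#'
#' @param d_iso Distance from the effective neutron source to isocenter (cm),
#'   strictly positive. Not a published quantity; a configuration value
#'   (default 230 cm, a typical gantry source-axis distance).
#' @param iso_depth Depth of the isocenter below the phantom surface (cm);
#'   0 for in-air geometries. Must satisfy `0 <= iso_depth < d_iso`.
#' @param environment `"in_water"` or `"in_air"`.
#' @return An object of class `beam_geometry`.
#' @export
#' @examples
#' beam_geometry(d_iso = 230, iso_depth = 22, environment = "in_water")
beam_geometry <- function(d_iso = 230, iso_depth = 22,
                          environment = c("in_water", "in_air")) {
  environment <- match.arg(environment)
  stop_unless(is_scalar_num(d_iso) && d_iso > 0, "`d_iso` must be positive (cm)")
  stop_unless(is_scalar_num(iso_depth) && iso_depth >= 0 && iso_depth < d_iso,
              "`iso_depth` must satisfy 0 <= iso_depth < d_iso (cm)")
  if (environment == "in_air" && iso_depth != 0) {
    stop("invalid configuration: `iso_depth` must be 0 for an in_air geometry",
         call. = FALSE)
  }
  structure(
    list(d_iso = d_iso, iso_depth = iso_depth, environment = environment),
    class = "beam_geometry"
  )
}

# --- internal helpers -------------------------------------------------------

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

regime_names <- function() c("direct", "evaporation", "epithermal", "thermal")
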