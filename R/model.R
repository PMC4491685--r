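#' Cumulative normal function
#'
#' Gaussian cumulative distribution used to model the onset of the
#' evaporation-neutron fraction with proton beam energy: the integral of a
#' normal density with the given mean and width, evaluated at `E`.
#'
#' @param E Proton beam energy (MeV); vectorized.
#' @param mean Mean of the Gaussian (MeV).
#' @param width Width (standard deviation) of the Gaussian (MeV), > 0.
#' @return Fraction(s) in `[0, 1]`, monotone non-decreasing in `E`.
#' @export
#' @examples
#' cnorm(130, 130, 5) # 0.5 by symmetry
cnorm <- function(E, mean, width) {
  stop_unless(is_scalar_num(width) && width > 0,
              "invalid parameter: `width` must be a positive number (MeV)")
  stop_unless(is_scalar_num(mean), "`mean` must be a number (MeV)")
  stats::pnorm(E, mean = mean, sd = width)
}

#' Regime fractions at given proton energies
#'
#' Evaluates the four neutron-regime apportionment fractions at each energy.
#' For a [regime_apportionment()] the fractions follow the energy-dependent
#' forms (linear, bounded cumulative normal, constant, quadratic); for a
#' [scalar_apportionment()] they are constant. With renormalization on, the
#' fractions are divided by their raw sum so they total exactly 1.
#'
#' A raw evaporation fraction below zero (possible because its published
#' lower bound is a numerically negligible negative number) is clipped at 0
#' with a warning; a negative raw fraction for any other regime is an error.
#'
#' @param E Proton beam energies (MeV).
#' @param app A [regime_apportionment()] or [scalar_apportionment()].
#' @param renormalize Override the apportionment's renormalize flag.
#' @return A tibble with columns `energy_MeV`, `direct`, `evaporation`,
#'   `epithermal`, `thermal`.
#' @export
#' @examples
#' app <- regime_apportionment(-4.8e-4, 0.6, 0.12, 130, 5, -1.3e-11,
#'                             0.4, 1.2e-7, -6.6e-5, 1.1e-2)
#' regime_fractions(c(100, 250), app)
regime_fractions <- function(E, app, renormalize = NULL) {
  Cmat <- regime_fraction_matrix(E, app, renormalize = renormalize)
  out <- tibble::as_tibble(as.data.frame(Cmat))
  names(out) <- regime_names()
  dplyr::bind_cols(tibble::tibble(energy_MeV = as.numeric(E)), out)
}

# n x 4 matrix of regime fractions; the numeric workhorse behind
# regime_fractions() and the dose evaluators. `quiet` suppresses the
# clip/energy-range warnings (used inside optimizer objectives). With
# `clip = TRUE` all negative raw fractions are silently clipped at zero and
# the mean squared violation is attached as attr "violation": the fitting
# objective stays continuous across the feasibility boundary and penalizes
# the violation instead of erroring.
regime_fraction_matrix <- function(E, app, renormalize = NULL, quiet = FALSE,
                                   clip = FALSE) {
  stop_unless(is.numeric(E) && length(E) >= 1L && all(is.finite(E)),
              "`E` must be numeric (MeV)")
  n <- length(E)
  if (inherits(app, "scalar_apportionment")) {
    C <- matrix(c(app$C1, app$C2, app$C3, app$C4), nrow = n, ncol = 4,
                byrow = TRUE)
  } else if (inherits(app, "regime_apportionment")) {
    if (!quiet && (any(E < app$energy_range[1]) || any(E > app$energy_range[2]))) {
      warning(sprintf("energy outside the supported range [%g, %g] MeV; the parameterization is extrapolated",
                      app$energy_range[1], app$energy_range[2]), call. = FALSE)
    }
    C <- cbind(
      app$a1 * E + app$b1,
      app$a2 * cnorm(E, app$b2, app$c2) + app$d2,
      rep(app$a3, n),
      app$a4 * E^2 + app$b4 * E + app$c4
    )
    violation <- 0
    if (clip) {
      violation <- mean(pmax(-C[, c(1L, 3L, 4L)], 0)^2)
      C <- pmax(C, 0)
    } else {
      if (any(C[, 2] < 0)) {
        if (!quiet) {
          warning("raw evaporation fraction below 0 clipped at 0 (lower bound d2 is negative)",
                  call. = FALSE)
        }
        C[, 2] <- pmax(C[, 2], 0)
      }
      for (i in c(1L, 3L, 4L)) {
        if (any(C[, i] < 0)) {
          bad <- E[which(C[, i] < 0)[1]]
          stop(sprintf("invalid parameter: raw fraction for the %s regime is negative at E = %g MeV",
                       regime_names()[i], bad), call. = FALSE)
        }
      }
    }
  } else {
    stop("`app` must be a regime_apportionment or scalar_apportionment",
         call. = FALSE)
  }
  if (is.null(renormalize)) renormalize <- app$renormalize
  if (renormalize) C <- normalize_rows(C)
  if (clip) attr(C, "violation") <- if (exists("violation", inherits = FALSE)) violation else 0
  C
}

# Divide each row by its sum, then push the (at most one-ulp) rounding
# residual into the largest component so the plain left-to-right double sum
# of each row is exactly 1 (the evaluator accumulates regimes in that order).
normalize_rows <- function(C) {
  s <- rowSums(C)
  if (any(s <= 0)) {
    stop("invalid parameter: regime fractions sum to zero; cannot renormalize",
         call. = FALSE)
  }
  Cn <- C / s
  # replace the last fraction by the exact complement of the first three:
  # fl(S3 + (1 - S3)) == 1 in double arithmetic, so the left-to-right sum
  # the evaluator computes is exactly 1; the perturbation is O(ulp)
  Cn[, 4] <- 1 - ((Cn[, 1] + Cn[, 2]) + Cn[, 3])
  Cn
}

#' Isocenter H/D as a function of proton beam energy
#'
#' Evaluates the power-law calibration
#' `alpha_E * E^p_E * hd_ref_iso` (Sv/Gy).
#'
#' @param E Proton beam energies (MeV), all > 0.
#' @param cal An [energy_calibration()].
#' @return H/D at isocenter (Sv/Gy), one value per energy.
#' @export
#' @examples
#' hd_iso(250, energy_calibration(8.0e-9, 4.1, 1.2e-4))
hd_iso <- function(E, cal) {
  stop_unless(inherits(cal, "energy_calibration"),
              "`cal` must be an energy_calibration")
  stop_unless(is.numeric(E) && all(is.finite(E)), "`E` must be numeric (MeV)")
  if (any(E <= 0)) stop("invalid input: proton energy must be positive", call. = FALSE)
  cal$alpha_E * E^cal$p_E * cal$hd_ref_iso
}

#' Ray distances from the effective neutron source through the phantom
#'
#' For each evaluation point, computes the source-to-point distance `d`, the
#' in-phantom path length `d_prime` from the phantom surface to the point
#' along that ray, and the in-phantom path length to isocenter
#' `d_prime_iso`. The phantom entrance plane is at axial distance
#' `d_iso - iso_depth` from the source; in-air geometries have no phantom,
#' so both in-phantom path lengths are zero.
#'
#' @param points A data frame with columns `x_cm`, `y_cm` (lateral offsets
#'   from the beam axis) and `z_cm` (axial distance from the source to the
#'   point's transverse plane), all in cm; `z_cm > 0`.
#' @param geom A [beam_geometry()].
#' @return The input as a tibble with columns `d_cm`, `d_prime_cm` and
#'   `d_prime_iso_cm` appended.
#' @export
#' @examples
#' geom <- beam_geometry(230, 22, "in_water")
#' ray_distances(tibble::tibble(x_cm = 10, y_cm = 0, z_cm = 230), geom)
ray_distances <- function(points, geom) {
  points <- check_points(points)
  stop_unless(inherits(geom, "beam_geometry"), "`geom` must be a beam_geometry")
  d <- sqrt(points$x_cm^2 + points$y_cm^2 + points$z_cm^2)
  if (geom$environment == "in_air") {
    d_prime <- rep(0, nrow(points))
    d_prime_iso <- 0
  } else {
    z_surface <- geom$d_iso - geom$iso_depth
    # (d/z) * (z - z_surface) rather than d * (1 - z_surface/z): cancels
    # exactly on the axis so the isocenter attenuation factor is exactly 1
    d_prime <- (d / points$z_cm) * pmax(0, points$z_cm - z_surface)
    d_prime_iso <- geom$iso_depth
  }
  dplyr::mutate(tibble::as_tibble(points),
                d_cm = d, d_prime_cm = d_prime, d_prime_iso_cm = d_prime_iso)
}

check_points <- function(points) {
  stop_unless(is.data.frame(points), "`points` must be a data frame")
  missing <- setdiff(c("x_cm", "y_cm", "z_cm"), names(points))
  if (length(missing)) {
    stop("`points` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(points$z_cm <= 0)) {
    stop("invalid input: `z_cm` must be positive (the lateral term divides by z^2)",
         call. = FALSE)
  }
  points
}

#' Leakage-neutron H/D at points in a water phantom
#'
#' Evaluates the analytical model of neutron equivalent dose per therapeutic
#' absorbed dose at each point: the isocenter H/D at the requested energy,
#' scaled by a power-law falloff in source distance and, per neutron regime,
#' exponential attenuation along the in-phantom path (relative to the
#' isocenter path) and a Gaussian lateral profile whose width grows linearly
#' with axial distance. At the isocenter, with renormalization on, every
#' spatial factor is 1 and the total equals the isocenter calibration value
#' exactly.
#'
#' @inheritParams ray_distances
#' @param E Proton beam energy (MeV); a scalar or one value per point.
#' @param cal An [energy_calibration()].
#' @param app A [regime_apportionment()].
#' @param tp A [transport_parameters()].
#' @return A tibble: the input points plus `energy_MeV`, the total
#'   `hd_Sv_per_Gy`, and per-regime columns `hd_direct_Sv_per_Gy`,
#'   `hd_evaporation_Sv_per_Gy`, `hd_epithermal_Sv_per_Gy`,
#'   `hd_thermal_Sv_per_Gy`.
#' @seealso [hd_point_in_air()], [evaluate_hd()]
#' @export
hd_point <- function(points, geom, E, cal, app, tp) {
  stop_unless(inherits(geom, "beam_geometry"), "`geom` must be a beam_geometry")
  if (geom$environment != "in_water") {
    stop("invalid configuration: hd_point() requires an in_water geometry; use hd_point_in_air()",
         call. = FALSE)
  }
  stop_unless(inherits(app, "regime_apportionment"),
              "`app` must be a regime_apportionment")
  points <- check_points(points)
  n <- nrow(points)
  E <- recycle_energy(E, n)
  Cmat <- regime_fraction_matrix(E, app)
  hd_eval_core(points, geom, E, hd_iso(E, cal), Cmat, tp)
}

#' Leakage-neutron H/D at points in air (single-energy ocular variant)
#'
#' In-air variant of the model: the isocenter H/D is a measured scalar, the
#' regime fractions are scalars, and the water attenuation coefficients are
#' all zero (no phantom), so the attenuation factors are exactly 1.
#'
#' @inheritParams ray_distances
#' @param hd_iso_measured Measured H/D at isocenter (Sv/Gy), > 0.
#' @param app A [scalar_apportionment()].
#' @param tp A [transport_parameters()] with all attenuation coefficients 0.
#' @param energy Beam energy label recorded in the output (MeV); default `NA`.
#' @return A tibble as in [hd_point()].
#' @export
hd_point_in_air <- function(points, geom, hd_iso_measured, app, tp,
                            energy = NA_real_) {
  stop_unless(inherits(geom, "beam_geometry"), "`geom` must be a beam_geometry")
  if (geom$environment != "in_air") {
    stop("invalid configuration: hd_point_in_air() requires an in_air geometry",
         call. = FALSE)
  }
  stop_unless(inherits(app, "scalar_apportionment"),
              "`app` must be a scalar_apportionment")
  stop_unless(inherits(tp, "transport_parameters"),
              "`tp` must be a transport_parameters")
  if (any(tp$alpha != 0)) {
    stop("invalid configuration: attenuation coefficients must all be zero in air",
         call. = FALSE)
  }
  stop_unless(is_scalar_num(hd_iso_measured) && hd_iso_measured > 0,
              "`hd_iso_measured` must be positive (Sv/Gy)")
  points <- check_points(points)
  n <- nrow(points)
  Cmat <- regime_fraction_matrix(rep(1, n), app)
  hd_eval_core(points, geom, rep(as.numeric(energy), n),
               rep(hd_iso_measured, n), Cmat, tp)
}

# Numeric evaluator: hd_iso(E) * (d/d_iso)^-q *
#   sum_i C_i * exp(-alpha_i (d' - d'_iso)) * exp(-(x^2+y^2) d_iso^2 / (2 sigma_i^2 z^2))
# Plain vectors/matrix in and out; called thousands of times per fit.
hd_eval_values <- function(x, y, z, geom, hd_iso_vals, Cmat, tp) {
  d <- sqrt(x^2 + y^2 + z^2)
  if (geom$environment == "in_air") {
    delta <- 0
  } else {
    z_surface <- geom$d_iso - geom$iso_depth
    # (d/z) * (z - z_surface) rather than d * (1 - z_surface/z): cancels
    # exactly on the axis so the isocenter attenuation factor is exactly 1
    delta <- (d / z) * pmax(0, z - z_surface) - geom$iso_depth
  }
  distfac <- (d / geom$d_iso)^(-tp$q)
  latarg <- (x^2 + y^2) * geom$d_iso^2 / (2 * z^2)
  n <- length(d)
  per <- matrix(NA_real_, n, 4)
  inner <- numeric(n)
  for (i in 1:4) {
    factor_i <- Cmat[, i] * exp(-tp$alpha[i] * delta) * exp(-latarg / tp$sigma[i]^2)
    inner <- inner + factor_i
    per[, i] <- hd_iso_vals * distfac * factor_i
  }
  list(total = hd_iso_vals * distfac * inner, per = per)
}

# Tibble-building wrapper around hd_eval_values()
hd_eval_core <- function(points, geom, E, hd_iso_vals, Cmat, tp) {
  stop_unless(inherits(tp, "transport_parameters"),
              "`tp` must be a transport_parameters")
  vals <- hd_eval_values(points$x_cm, points$y_cm, points$z_cm, geom,
                         hd_iso_vals, Cmat, tp)
  out <- tibble::as_tibble(points)
  out$energy_MeV <- E
  out$hd_Sv_per_Gy <- vals$total
  per <- vals$per
  colnames(per) <- paste0("hd_", regime_names(), "_Sv_per_Gy")
  dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(per)))
}

recycle_energy <- function(E, n) {
  stop_unless(is.numeric(E) && all(is.finite(E)), "`E` must be numeric (MeV)")
  if (length(E) == 1L) E <- rep(E, n)
  stop_unless(length(E) == n, "`E` must be a scalar or one value per point")
  E
}

#' Evaluate a beamline configuration at points
#'
#' High-level, pipe-friendly entry point: evaluates a [beamline_config()] at
#' a set of points, dispatching to the in-water energy-dependent model or
#' the in-air single-energy variant as appropriate.
#'
#' @inheritParams ray_distances
#' @param config A [beamline_config()] (e.g. from [beamline_preset()] or
#'   [load_config()]).
#' @param energy Proton beam energy (MeV). Required for a general-purpose
#'   (in-water) configuration; for an ocular (in-air) configuration it
#'   defaults to the configuration's beam energy.
#' @return A tibble as in [hd_point()].
#' @export
#' @examples
#' cfg <- beamline_preset("general_purpose_100_250")
#' pts <- tibble::tibble(x_cm = c(0, 10), y_cm = 0, z_cm = 230)
#' evaluate_hd(pts, cfg, energy = 200)
evaluate_hd <- function(points, config, energy = NULL) {
  stop_unless(inherits(config, "beamline_config"), "`config` must be a beamline_config")
  if (config$geometry$environment == "in_air") {
    if (is.null(energy)) energy <- config$energy
    hd_point_in_air(points, config$geometry, config$hd_iso, config$apportionment,
                    config$transport, energy = energy)
  } else {
    if (is.null(energy)) {
      stop("`energy` (MeV) is required for an in-water configuration", call. = FALSE)
    }
    hd_point(points, config$geometry, energy, config$calibration,
             config$apportionment, config$transport)
  }
}
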