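#' Specification of an in-phantom detector grid
#'
#' Describes a grid of point detectors in the water phantom: several lines
#' parallel to the beam axis at fixed off-axis distances, plus (optionally)
#' one line perpendicular to the beam axis at a fixed depth. The default
#' reproduces the 100-detector layout used to characterize a general-purpose
#' beamline: 20 detectors on each of four longitudinal lines at 0, 10, 40 and
#' 80 cm off-axis (depths spanning 2-40 cm) and 20 on a lateral line at the
#' 22 cm isocenter depth.
#'
#' @param offsets_cm Off-axis distances of the longitudinal lines (cm), >= 0.
#' @param detectors_per_line Detectors on each line (longitudinal and lateral).
#' @param depth_range_cm Length-2 depth range of the longitudinal lines (cm).
#' @param lateral_depth_cm Depth of the lateral line (cm); `NULL` for no
#'   lateral line.
#' @param lateral_extent_cm Largest off-axis distance on the lateral line (cm).
#' @param phantom_depth_cm,phantom_halfwidth_cm Phantom bounds used to check
#'   that every detector lies inside the phantom.
#' @return An object of class `grid_spec`.
#' @seealso [mdacc_grid()]
#' @export
grid_spec <- function(offsets_cm = c(0, 10, 40, 80),
                      detectors_per_line = 20,
                      depth_range_cm = c(2, 40),
                      lateral_depth_cm = 22,
                      lateral_extent_cm = 80,
                      phantom_depth_cm = 60,
                      phantom_halfwidth_cm = 100) {
  stop_unless(is.numeric(offsets_cm) && length(offsets_cm) >= 1L && all(offsets_cm >= 0),
              "`offsets_cm` must be non-negative off-axis distances (cm)")
  stop_unless(is_scalar_num(detectors_per_line) && detectors_per_line >= 1,
              "`detectors_per_line` must be a positive count")
  stop_unless(is.numeric(depth_range_cm) && length(depth_range_cm) == 2L &&
                depth_range_cm[1] > 0 && depth_range_cm[1] <= depth_range_cm[2],
              "`depth_range_cm` must be an increasing pair of positive depths (cm)")
  if (!is.null(lateral_depth_cm)) {
    stop_unless(is_scalar_num(lateral_depth_cm) && lateral_depth_cm > 0,
                "`lateral_depth_cm` must be a positive depth (cm)")
    stop_unless(is_scalar_num(lateral_extent_cm) && lateral_extent_cm > 0,
                "`lateral_extent_cm` must be a positive distance (cm)")
  }
  spec <- structure(
    list(offsets_cm = offsets_cm,
         detectors_per_line = as.integer(detectors_per_line),
         depth_range_cm = depth_range_cm,
         lateral_depth_cm = lateral_depth_cm,
         lateral_extent_cm = lateral_extent_cm,
         phantom_depth_cm = phantom_depth_cm,
         phantom_halfwidth_cm = phantom_halfwidth_cm),
    class = "grid_spec"
  )
  if (spec$depth_range_cm[2] > spec$phantom_depth_cm ||
      max(spec$offsets_cm) > spec$phantom_halfwidth_cm ||
      (!is.null(lateral_depth_cm) &&
         (lateral_depth_cm > spec$phantom_depth_cm ||
            lateral_extent_cm > spec$phantom_halfwidth_cm))) {
    stop("invalid grid spec: detector positions fall outside the phantom",
         call. = FALSE)
  }
  spec
}

#' Detector grid in the water phantom
#'
#' Lays out the in-phantom detector positions described by a [grid_spec()]
#' in source-centered coordinates (the axial coordinate of a point at depth
#' `t` is `d_iso - iso_depth + t`). With the defaults this yields exactly
#' 100 points: 4 longitudinal lines of 20 detectors plus one lateral line of
#' 20 detectors at isocenter depth. Lateral-line positions are evenly spaced
#' from `lateral_extent_cm / detectors_per_line` to `lateral_extent_cm`
#' (starting off-axis, since the on-axis position at that depth already lies
#' on the first longitudinal line).
#'
#' @param spec A [grid_spec()].
#' @param geom A [beam_geometry()] with an in-water environment.
#' @return A tibble with columns `x_cm`, `y_cm`, `z_cm`, `depth_cm` and a
#'   `line` label.
#' @export
#' @examples
#' nrow(mdacc_grid()) # 100
mdacc_grid <- function(spec = grid_spec(), geom = beam_geometry()) {
  stop_unless(inherits(spec, "grid_spec"), "`spec` must be a grid_spec")
  stop_unless(inherits(geom, "beam_geometry") && geom$environment == "in_water",
              "`geom` must be an in-water beam_geometry")
  z_surface <- geom$d_iso - geom$iso_depth
  n <- spec$detectors_per_line
  depths <- if (n == 1L) spec$depth_range_cm[1] else
    seq(spec$depth_range_cm[1], spec$depth_range_cm[2], length.out = n)
  long <- tidyr::expand_grid(x_cm = spec$offsets_cm, depth_cm = depths) |>
    dplyr::mutate(y_cm = 0,
                  z_cm = z_surface + .data$depth_cm,
                  line = sprintf("longitudinal_%gcm", .data$x_cm))
  out <- long
  if (!is.null(spec$lateral_depth_cm)) {
    lat_x <- seq(spec$lateral_extent_cm / n, spec$lateral_extent_cm, length.out = n)
    lat <- tibble::tibble(x_cm = lat_x, depth_cm = spec$lateral_depth_cm,
                          y_cm = 0,
                          z_cm = z_surface + spec$lateral_depth_cm,
                          line = "lateral")
    out <- dplyr::bind_rows(long, lat)
  }
  dplyr::select(out, "x_cm", "y_cm", "z_cm", "depth_cm", "line")
}

#' In-air measurement positions around an ocular beamline
#'
#' Points along three rays from the isocenter at 0 degrees (along the beam
#' axis, distal to isocenter), 45 degrees and 90 degrees to the beam axis,
#' in source-centered coordinates. The defaults give the 10 positions used
#' to survey the ocular beamline (4 on-axis at 25-100 cm, 3 on each oblique
#' ray at 25-75 cm); the specific distances are configuration values, not
#' published quantities.
#'
#' @param d_iso Source-to-isocenter distance (cm).
#' @param axis_distances_cm Distances from isocenter along the 0-degree ray (cm).
#' @param oblique_distances_cm Distances from isocenter along the 45- and
#'   90-degree rays (cm).
#' @return A tibble with columns `x_cm`, `y_cm`, `z_cm`, `ray` and
#'   `r_iso_cm` (distance from isocenter).
#' @export
#' @examples
#' ocular_positions()
ocular_positions <- function(d_iso = 100,
                             axis_distances_cm = c(25, 50, 75, 100),
                             oblique_distances_cm = c(25, 50, 75)) {
  stop_unless(is_scalar_num(d_iso) && d_iso > 0, "`d_iso` must be positive (cm)")
  stop_unless(is.numeric(axis_distances_cm) && all(axis_distances_cm > 0),
              "`axis_distances_cm` must be positive (cm)")
  stop_unless(is.numeric(oblique_distances_cm) && all(oblique_distances_cm > 0),
              "`oblique_distances_cm` must be positive (cm)")
  ray_points <- function(r, angle_deg) {
    theta <- angle_deg * pi / 180
    tibble::tibble(x_cm = r * sin(theta), y_cm = 0,
                   z_cm = d_iso + r * cos(theta),
                   ray = sprintf("%gdeg", angle_deg), r_iso_cm = r)
  }
  dplyr::bind_rows(
    ray_points(axis_distances_cm, 0),
    ray_points(oblique_distances_cm, 45),
    ray_points(oblique_distances_cm, 90)
  )
}

#' Multiplicative noise model for synthetic H/D data
#'
#' @param rel_sd Relative standard deviation of the noise (fraction of the
#'   true value); 0 means noiseless.
#' @param distribution `"gaussian"` (factor `1 + rel_sd * Z`) or
#'   `"lognormal"` (unit-mean log-normal factor whose relative sd matches
#'   `rel_sd` at first order).
#' @param seed Integer seed for reproducible draws; `NULL` uses the current
#'   RNG state.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(rel_sd = 0, distribution = c("gaussian", "lognormal"),
                        seed = NULL) {
  distribution <- match.arg(distribution)
  stop_unless(is_scalar_num(rel_sd) && rel_sd >= 0,
              "`rel_sd` must be a non-negative fraction")
  if (!is.null(seed)) stop_unless(is_scalar_num(seed), "`seed` must be an integer")
  structure(list(rel_sd = rel_sd, distribution = distribution, seed = seed),
            class = "noise_model")
}

noise_factors <- function(n, noise) {
  if (noise$rel_sd == 0) return(rep(1, n))
  draw <- function() {
    if (noise$distribution == "gaussian") {
      f <- 1 + noise$rel_sd * stats::rnorm(n)
      # H/D is strictly positive; redraw the (vanishingly rare) non-positive factors
      while (any(f <= 0)) {
        bad <- which(f <= 0)
        f[bad] <- 1 + noise$rel_sd * stats::rnorm(length(bad))
      }
      f
    } else {
      sdlog <- sqrt(log1p(noise$rel_sd^2))
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
  }
  if (is.null(noise$seed)) draw() else withr::with_seed(as.integer(noise$seed), draw())
}

#' Generate a synthetic H/D dataset from a beamline configuration
#'
#' Evaluates the analytical model at the given points (and, for an in-water
#' configuration, at each requested energy) and multiplies the values by
#' noise factors. The result is a model-based surrogate for a Monte Carlo or
#' measurement campaign; with `rel_sd = 0` the generation is bit-reproducible
#' and seeded generation is reproducible across runs.
#'
#' @inheritParams ray_distances
#' @param config A [beamline_config()].
#' @param energies Proton beam energies (MeV) at which to evaluate an
#'   in-water configuration; defaults to the eight nominal energies
#'   100, 120, 140, 160, 180, 200, 225, 250. Ignored (with the configured
#'   beam energy used instead) for an in-air configuration.
#' @param noise A [noise_model()].
#' @return A dose-dataset tibble with columns `x_cm`, `y_cm`, `z_cm`,
#'   `energy_MeV`, `environment`, `hd_Sv_per_Gy`.
#' @export
#' @examples
#' cfg <- beamline_preset("general_purpose_100_250")
#' ds <- generate_dataset(mdacc_grid(), cfg, energies = c(100, 250))
generate_dataset <- function(points, config, energies = NULL,
                             noise = noise_model()) {
  stop_unless(inherits(config, "beamline_config"), "`config` must be a beamline_config")
  stop_unless(inherits(noise, "noise_model"), "`noise` must be a noise_model")
  points <- check_points(points)
  if (config$geometry$environment == "in_air") {
    ev <- evaluate_hd(points, config)
  } else {
    if (is.null(energies)) energies <- c(100, 120, 140, 160, 180, 200, 225, 250)
    ev <- purrr::map(energies, function(E) evaluate_hd(points, config, energy = E)) |>
      dplyr::bind_rows()
  }
  out <- tibble::tibble(
    x_cm = ev$x_cm, y_cm = ev$y_cm, z_cm = ev$z_cm,
    energy_MeV = ev$energy_MeV,
    environment = config$geometry$environment,
    hd_Sv_per_Gy = ev$hd_Sv_per_Gy * noise_factors(nrow(ev), noise)
  )
  attr(out, "provenance") <- "synthetic"
  out
}
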