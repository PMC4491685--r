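# Shared fixtures: shipped presets and small noiseless datasets, built once
# per test run. Everything is generated in code; no stored data files.

gp_config <- beamline_preset("general_purpose_100_250")
oc_config <- beamline_preset("ocular_75MeV")

gp_grid <- mdacc_grid()
gp_dataset <- generate_dataset(gp_grid, gp_config)

oc_points_dense <- ocular_positions(d_iso = oc_config$geometry$d_iso,
                                    axis_distances_cm = seq(10, 100, by = 10),
                                    oblique_distances_cm = seq(10, 100, by = 10))
oc_dataset <- generate_dataset(ocular_positions(), oc_config)
oc_dataset_dense <- generate_dataset(oc_points_dense, oc_config)

# Independent quadrature oracle for the cumulative normal: integrate the
# Gaussian density directly rather than calling any distribution function.
cnorm_quadrature <- function(E, mean, width) {
  dens <- function(t) exp(-(t - mean)^2 / (2 * width^2)) / (width * sqrt(2 * pi))
  # integrate the smaller tail so the quadrature never misses the bump
  if (E >= mean) {
    1 - stats::integrate(dens, lower = E, upper = Inf,
                         rel.tol = 1e-13, abs.tol = 1e-13)$value
  } else {
    stats::integrate(dens, lower = -Inf, upper = E,
                     rel.tol = 1e-13, abs.tol = 1e-13)$value
  }
}

fast_fit <- function(multi_start = 2, seed = 1905, ...) {
  fit_config(multi_start = multi_start, seed = seed, ...)
}
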