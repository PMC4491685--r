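test_that("cnorm matches an independent quadrature of the Gaussian integral", {
  # symmetry about the mean
  expect_equal(cnorm(130, 130, 5), 0.5)
  # frozen value from the quadrature oracle: one width above the mean
  expect_equal(cnorm(135, 130, 5), 0.84134474606854293, tolerance = 1e-10)
  # limits
  expect_lt(cnorm(-1e6, 130, 5), 1e-12)
  expect_gt(cnorm(1e6, 130, 5), 1 - 1e-12)
  # grid agreement with quadrature
  for (m in c(110, 130, 160)) {
    for (w in c(2, 5, 20)) {
      for (E in seq(80, 280, by = 40)) {
        expect_lt(abs(cnorm(E, m, w) - cnorm_quadrature(E, m, w)), 1e-10)
      }
    }
  }
  # monotone non-decreasing in E
  Es <- seq(50, 300, by = 5)
  expect_true(all(diff(cnorm(Es, 130, 5)) >= 0))
  expect_error(cnorm(130, 130, 0), "positive")
  expect_error(cnorm(130, 130, -2), "positive")
})

test_that("raw regime fractions reproduce the published coefficient forms", {
  app <- gp_config$apportionment
  fr250 <- regime_fractions(250, app, renormalize = FALSE)
  expect_equal(fr250$direct, -4.8e-4 * 250 + 0.6)            # 0.48
  expect_equal(fr250$epithermal, 0.4)
  fr100 <- regime_fractions(100, app, renormalize = FALSE)
  expect_equal(fr100$thermal, 1.2e-7 * 100^2 - 6.6e-5 * 100 + 1.1e-2) # 0.0056
  expect_equal(fr100$epithermal, 0.4)
  # evaporation fraction follows the bounded cumulative normal
  expect_equal(fr250$evaporation, 0.12 * cnorm_quadrature(250, 130, 5) - 1.3e-11,
               tolerance = 1e-10)
})

test_that("renormalized fractions sum to unity across a dense energy scan", {
  Es <- seq(100, 250, by = 1)
  fr <- regime_fractions(Es, gp_config$apportionment, renormalize = TRUE)
  sums <- rowSums(as.matrix(fr[, c("direct", "evaporation", "epithermal", "thermal")]))
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(as.matrix(fr[, -1]) >= 0))
  # scalar variant too
  frs <- regime_fractions(75, oc_config$apportionment, renormalize = TRUE)
  expect_lt(abs(sum(as.matrix(frs[, -1])) - 1), 1e-12)
})

test_that("negative raw fractions are rejected (or clipped for evaporation)", {
  bad <- regime_apportionment(a1 = -4.8e-4, b1 = 0.05, a2 = 0.12, b2 = 130,
                              c2 = 5, d2 = 0, a3 = 0.4, a4 = 1.2e-7,
                              b4 = -6.6e-5, c4 = 1.1e-2)
  expect_error(regime_fractions(250, bad), "direct")
  # below ~98 MeV the published evaporation curve dips below zero: clipped
  expect_warning(
    expect_warning(regime_fractions(75, gp_config$apportionment), "clipped"),
    "outside the supported range"
  )
  fr <- suppressWarnings(regime_fractions(75, gp_config$apportionment,
                                          renormalize = FALSE))
  expect_identical(fr$evaporation, 0)
  expect_error(scalar_apportionment(0.1, -0.2, 0.4, 0.3), "evaporation")
})

test_that("isocenter calibration follows the power law exactly", {
  cal <- gp_config$calibration
  # frozen log-domain oracle: exp(log a + p log E + log hd_ref) at 250 MeV
  expect_equal(hd_iso(250, cal),
               exp(log(8.0e-9) + 4.1 * log(250) + log(1.2e-4)),
               tolerance = 1e-12)
  expect_equal(hd_iso(250, cal), 6.5e-3, tolerance = 0.02)
  # ratio identity and exact scaling
  expect_equal(hd_iso(200, cal) / hd_iso(100, cal), 2^4.1, tolerance = 1e-12)
  for (k in c(0.5, 1.7, 3)) {
    expect_equal(hd_iso(k * 120, cal), k^cal$p_E * hd_iso(120, cal),
                 tolerance = 1e-12)
  }
  # self-consistent construction pins the reference point
  sc <- self_consistent_calibration(p_E = 4.1, hd_ref_iso = 1.2e-4, ref_energy = 100)
  expect_equal(hd_iso(100, sc), 1.2e-4, tolerance = 1e-14)
  expect_error(hd_iso(0, cal), "positive")
  expect_error(hd_iso(-50, cal), "positive")
})

test_that("isocenter H/D is the closed/open collimator yield quotient", {
  expect_equal(hd_ref_iso_from_yields(1.2e-16, 1.0e-12), 1.2e-4)
  expect_equal(hd_ref_iso_from_yields(0, 1e-12), 0)
  expect_equal(hd_ref_iso_from_yields(2 * 1.2e-16, 2 * 1.0e-12),
               hd_ref_iso_from_yields(1.2e-16, 1.0e-12))
  expect_error(hd_ref_iso_from_yields(1e-16, 0), "positive")
  expect_error(hd_ref_iso_from_yields(1e-16, -1e-12), "positive")
})

test_that("ray distances follow the source-surface-point geometry", {
  geom <- gp_config$geometry
  iso <- ray_distances(tibble::tibble(x_cm = 0, y_cm = 0, z_cm = 230), geom)
  expect_equal(iso$d_cm, 230)
  expect_equal(iso$d_prime_cm, 22)
  expect_equal(iso$d_prime_iso_cm, 22)
  # hand trigonometry along an oblique ray
  d_exp <- sqrt(10^2 + 230^2)
  off <- ray_distances(tibble::tibble(x_cm = 10, y_cm = 0, z_cm = 230), geom)
  expect_equal(off$d_cm, d_exp, tolerance = 1e-12)
  expect_equal(off$d_prime_cm, d_exp * (1 - 208 / 230), tolerance = 1e-12)
  expect_equal(round(off$d_cm, 3), 230.217)
  expect_equal(round(off$d_prime_cm, 2), 22.02)
  # a point upstream of the phantom surface has no in-phantom path
  up <- ray_distances(tibble::tibble(x_cm = 0, y_cm = 0, z_cm = 100), geom)
  expect_equal(up$d_prime_cm, 0)
  # in-air: no phantom material anywhere
  air <- ray_distances(tibble::tibble(x_cm = 30, y_cm = 0, z_cm = 150),
                       oc_config$geometry)
  expect_identical(air$d_prime_cm, 0)
  expect_identical(air$d_prime_iso_cm, 0)
  expect_error(ray_distances(tibble::tibble(x_cm = 0, y_cm = 0, z_cm = 0), geom),
               "z_cm")
})

test_that("in-water H/D at the isocenter equals the calibration bit-identically", {
  pt <- tibble::tibble(x_cm = 0, y_cm = 0, z_cm = gp_config$geometry$d_iso)
  for (E in c(100, 140, 180, 250)) {
    r <- evaluate_hd(pt, gp_config, energy = E)
    expect_identical(r$hd_Sv_per_Gy, hd_iso(E, gp_config$calibration))
  }
})

test_that("off-axis in-water H/D matches a term-by-term hand evaluation", {
  # independent oracle: transcribe the point model factor by factor
  E <- 100
  hd0 <- 8.0e-9 * E^4.1 * 1.2e-4
  x <- 10; z <- 230; d_iso <- 230; iso_depth <- 22
  d <- sqrt(x^2 + z^2)
  dprime <- d * (1 - (d_iso - iso_depth) / z)
  Craw <- c(-4.8e-4 * E + 0.6,
            0.12 * stats::pnorm(E, 130, 5) - 1.3e-11,
            0.4,
            1.2e-7 * E^2 - 6.6e-5 * E + 1.1e-2)
  C <- Craw / sum(Craw)
  alpha <- c(0.013, 0.013, 0.032, 0.33)
  sigma <- c(14, 77, 3900, 3900)
  terms <- C * exp(-alpha * (dprime - iso_depth)) *
    exp(-x^2 * d_iso^2 / (2 * sigma^2 * z^2))
  expected <- hd0 * (d / d_iso)^(-1.13) * sum(terms)
  r <- evaluate_hd(tibble::tibble(x_cm = 10, y_cm = 0, z_cm = 230), gp_config,
                   energy = 100)
  expect_equal(r$hd_Sv_per_Gy, expected, tolerance = 1e-10)
  # frozen magnitude from the same oracle
  expect_equal(r$hd_Sv_per_Gy, 1.3219e-4, tolerance = 1e-3)
})

test_that("H/D decomposes into four non-negative regime components", {
  set.seed(11)
  pts <- tibble::tibble(x_cm = runif(40, 0, 80), y_cm = runif(40, -20, 20),
                        z_cm = runif(40, 210, 248))
  for (E in c(100, 175, 250)) {
    r <- evaluate_hd(pts, gp_config, energy = E)
    per <- as.matrix(r[, paste0("hd_", c("direct", "evaporation", "epithermal",
                                         "thermal"), "_Sv_per_Gy")])
    expect_true(all(per >= 0))
    expect_true(all(r$hd_Sv_per_Gy > 0))
    expect_equal(r$hd_Sv_per_Gy, rowSums(per), tolerance = 1e-12)
  }
})

test_that("degenerate transport parameters collapse the spatial factors", {
  # huge widths, no attenuation, vanishing falloff: H/D is flat at hd_iso
  flat_tp <- transport_parameters(alpha = c(0, 0, 0, 0), sigma = rep(1e9, 4),
                                  q = 1e-12)
  pts <- tibble::tibble(x_cm = c(0, 40, 80), y_cm = 0, z_cm = c(230, 215, 245))
  r <- hd_point(pts, gp_config$geometry, 160, gp_config$calibration,
                gp_config$apportionment, flat_tp)
  expect_equal(r$hd_Sv_per_Gy, rep(hd_iso(160, gp_config$calibration), 3),
               tolerance = 1e-9)
})

test_that("in-air ocular model reproduces the measured isocenter and falloff", {
  iso <- evaluate_hd(tibble::tibble(x_cm = 0, y_cm = 0, z_cm = 100), oc_config)
  expect_equal(iso$hd_Sv_per_Gy, 5.2e-5, tolerance = 1e-14)
  # pure power-law falloff on the beam axis
  far <- evaluate_hd(tibble::tibble(x_cm = 0, y_cm = 0, z_cm = 200), oc_config)
  expect_equal(far$hd_Sv_per_Gy, 5.2e-5 * 2^(-1.5), tolerance = 1e-12)
  # the attenuation factor is exactly 1 everywhere in air: scaling every
  # sigma to infinity leaves only the distance factor, at any angle
  tp_inf <- transport_parameters(alpha = c(0, 0, 0, 0), sigma = rep(1e12, 4),
                                 q = 1.5)
  oblique <- hd_point_in_air(
    tibble::tibble(x_cm = 200 * sin(pi / 3), y_cm = 0, z_cm = 200 * cos(pi / 3)),
    oc_config$geometry, 5.2e-5, oc_config$apportionment, tp_inf)
  expect_equal(oblique$hd_Sv_per_Gy, 5.2e-5 * 2^(-1.5), tolerance = 1e-9)
  # nonzero attenuation is rejected in air
  tp_bad <- transport_parameters(alpha = c(0.01, 0, 0, 0), sigma = rep(10, 4),
                                 q = 1.5)
  expect_error(hd_point_in_air(tibble::tibble(x_cm = 0, y_cm = 0, z_cm = 100),
                               oc_config$geometry, 5.2e-5,
                               oc_config$apportionment, tp_bad),
               "zero")
  # and the in-water evaluator refuses in-air geometry (and vice versa)
  expect_error(hd_point(tibble::tibble(x_cm = 0, y_cm = 0, z_cm = 100),
                        oc_config$geometry, 75, gp_config$calibration,
                        gp_config$apportionment, gp_config$transport),
               "in_water")
})

test_that("energies outside the supported range warn but evaluate", {
  expect_warning(
    regime_fractions(260, gp_config$apportionment),
    "outside the supported range"
  )
})
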