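test_that("the objective is the mean squared local relative residual", {
  # data generated from the model itself: perfect score
  expect_identical(hd_objective(gp_config, gp_dataset), 0)
  # single record with model = 1.1 * observed
  one <- gp_dataset[1, ]
  one$hd_Sv_per_Gy <- one$hd_Sv_per_Gy / 1.1
  expect_equal(hd_objective(gp_config, one), 0.1^2, tolerance = 1e-12)
  # model = 1.1 * observed everywhere: closed form 0.01
  scaled <- gp_dataset
  scaled$hd_Sv_per_Gy <- scaled$hd_Sv_per_Gy / 1.1
  expect_equal(hd_objective(gp_config, scaled), 0.01, tolerance = 1e-12)
  expect_equal(hd_objective(gp_config, scaled, type = "mean_absolute"), 0.1,
               tolerance = 1e-12)
  # purely relative: common rescaling of data and model leaves it unchanged
  rescaled_cfg <- gp_config
  rescaled_cfg$calibration$hd_ref_iso <- gp_config$calibration$hd_ref_iso * 37
  rescaled_data <- gp_dataset
  rescaled_data$hd_Sv_per_Gy <- rescaled_data$hd_Sv_per_Gy * 37
  expect_equal(hd_objective(rescaled_cfg, rescaled_data),
               hd_objective(gp_config, gp_dataset), tolerance = 1e-12)
  # non-positive observations are invalid
  bad <- gp_dataset
  bad$hd_Sv_per_Gy[3] <- 0
  expect_error(hd_objective(gp_config, bad), "positive")
})

test_that("error statistics report mean and max local relative error in percent", {
  st <- error_statistics(gp_config, gp_dataset)
  expect_equal(st$mean_pct, 0)
  expect_equal(st$max_pct, 0)
  expect_equal(nrow(st$per_energy), 8L)
  # two records with 10% and 60% local relative error
  two <- gp_dataset[1:2, ]
  two$hd_Sv_per_Gy <- two$hd_Sv_per_Gy / c(1.1, 1.6)
  st2 <- error_statistics(gp_config, two)
  expect_equal(st2$mean_pct, 35, tolerance = 1e-9)
  expect_equal(st2$max_pct, 60, tolerance = 1e-9)
  # +10% everywhere
  scaled <- gp_dataset
  scaled$hd_Sv_per_Gy <- scaled$hd_Sv_per_Gy / 1.1
  st3 <- error_statistics(gp_config, scaled)
  expect_equal(st3$mean_pct, 10, tolerance = 1e-9)
  expect_equal(st3$max_pct, 10, tolerance = 1e-9)
  # mean never exceeds max, also under random noise
  noisy <- generate_dataset(gp_grid, gp_config, energies = c(100, 250),
                            noise = noise_model(0.1, seed = 5))
  st4 <- error_statistics(gp_config, noisy)
  expect_lte(st4$mean_pct, st4$max_pct)
  expect_true(all(st4$per_energy$mean_pct <= st4$per_energy$max_pct))
  expect_error(error_statistics(gp_config, gp_dataset[0, ]), "empty")
})

test_that("noiseless single-parameter fits recover the generating values", {
  # each parameter freed on its own recovers to within 0.1 percent
  for (p in c("q", "p_E", "sigma1", "alpha1")) {
    fit <- fit_general(gp_dataset, gp_config, free = p, control = fast_fit())
    truth <- config_to_params(gp_config)[[p]]
    expect_lt(abs(fit$par[[p]] - truth) / truth, 1e-3)
    expect_true(fit$converged)
  }
})

test_that("fitted apportionments satisfy sum-to-unity at fit and scan energies", {
  fit <- fit_general(gp_dataset, gp_config, free = c("a1", "b1", "a3"),
                     control = fast_fit())
  Es <- c(unique(gp_dataset$energy_MeV), seq(100, 250, length.out = 25))
  fr <- regime_fractions(Es, fit$config$apportionment)
  sums <- rowSums(as.matrix(fr[, -1]))
  expect_lt(max(abs(sums - 1)), 1e-12)
})

test_that("multi-start fitting is deterministic for a fixed seed", {
  f1 <- fit_general(gp_dataset, gp_config, free = c("q", "p_E"),
                    control = fit_config(multi_start = 3, seed = 99))
  f2 <- fit_general(gp_dataset, gp_config, free = c("q", "p_E"),
                    control = fit_config(multi_start = 3, seed = 99))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$starts, f2$starts)
})

test_that("the solution is never worse than any start point", {
  fit <- fit_general(gp_dataset, gp_config, free = c("q", "sigma1"),
                     control = fit_config(multi_start = 4, seed = 12))
  expect_true(all(fit$objective <= fit$starts$start_objective))
  expect_true(all(fit$starts$final_objective <= fit$starts$start_objective))
})

test_that("ocular fitting honors its variant contract", {
  # q and widths free on dense noiseless rays: falloff exponent recovered
  fit <- fit_ocular(oc_dataset_dense, oc_config,
                    free = c("q", "sigma1", "sigma2", "sigma3", "sigma4"),
                    control = fast_fit())
  expect_lt(abs(fit$par[["q"]] - 1.5) / 1.5, 1e-3)
  # no degrees of freedom: perfect data scores zero, parameters unchanged
  f0 <- fit_ocular(oc_dataset, oc_config, free = character(0))
  expect_identical(f0$objective, 0)
  expect_identical(f0$par, config_to_params(oc_config))
  # descent: refit from a deliberately wrong falloff exponent
  start_wrong <- oc_config
  start_wrong$transport$q <- 1.0
  f1 <- fit_ocular(oc_dataset_dense, start_wrong, free = "q",
                   control = fast_fit())
  expect_lt(f1$objective, min(f1$starts$start_objective))
  expect_equal(f1$par[["q"]], 1.5, tolerance = 1e-3)
  # in-water records are rejected
  expect_error(fit_ocular(gp_dataset, oc_config), "environment mismatch")
  expect_error(fit_general(oc_dataset, gp_config, free = "q"),
               "environment mismatch")
  # the measured isocenter value is not a free parameter
  expect_error(fit_ocular(oc_dataset, oc_config, free = "hd_iso"), "fixed")
  expect_error(fit_general(gp_dataset, gp_config, free = "hd_ref_iso"), "fixed")
})

test_that("degenerate data cannot constrain a fit", {
  expect_error(fit_general(gp_dataset[1, ], gp_config, free = "q"),
               "underdetermined")
  expect_error(fit_general(gp_dataset[1:2, ], gp_config, free = c("q", "p_E")),
               "underdetermined")
})

test_that("parameter vectors round-trip through configurations", {
  p <- config_to_params(gp_config)
  expect_length(p, 22L)
  expect_equal(config_to_params(params_to_config(p, gp_config)), p)
  po <- config_to_params(oc_config)
  expect_length(po, 10L)
  expect_equal(config_to_params(params_to_config(po, oc_config)), po)
})

test_that("tidy and glance summarize a fit", {
  fit <- fit_general(gp_dataset, gp_config, free = "q", control = fast_fit())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 22L)
  expect_identical(td$term[td$free], "q")
  expect_true(all(is.na(td$lower[!td$free])))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_equal(gl$n_free, 1L)
  expect_lt(gl$mean_err_pct, 0.1)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
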