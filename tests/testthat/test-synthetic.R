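test_that("the default detector grid reproduces the published layout", {
  g <- mdacc_grid()
  expect_equal(nrow(g), 100L)
  expect_setequal(unique(g$x_cm[g$line != "lateral"]), c(0, 10, 40, 80))
  # lateral line sits at the isocenter depth
  lat <- g[g$line == "lateral", ]
  expect_equal(nrow(lat), 20L)
  expect_true(all(lat$depth_cm == 22))
  expect_true(all(lat$z_cm == 230))
  # all longitudinal depths within the configured range, inside the phantom
  expect_true(all(g$depth_cm >= 2 & g$depth_cm <= 40))
  # z is the axial source distance: surface (208 cm) plus depth
  expect_equal(g$z_cm, 208 + g$depth_cm)
})

test_that("grid layout is a pure function of its spec", {
  s <- grid_spec(offsets_cm = c(0, 10), detectors_per_line = 5,
                 lateral_depth_cm = NULL)
  g <- mdacc_grid(s)
  expect_equal(nrow(g), 10L)
  expect_identical(mdacc_grid(s), g)
  expect_error(grid_spec(depth_range_cm = c(2, 70)), "outside the phantom")
  expect_error(grid_spec(offsets_cm = c(0, 150)), "outside the phantom")
})

test_that("ocular measurement positions lie on the three rays", {
  pos <- ocular_positions()
  expect_equal(nrow(pos), 10L)
  expect_setequal(unique(pos$ray), c("0deg", "45deg", "90deg"))
  on_axis <- pos[pos$ray == "0deg", ]
  expect_equal(nrow(on_axis), 4L)
  expect_true(all(on_axis$x_cm == 0 & on_axis$y_cm == 0))
  expect_true(all(on_axis$z_cm > 100)) # distal to isocenter
  perp <- pos[pos$ray == "90deg", ]
  expect_true(all(perp$z_cm == 100)) # isocenter transverse plane
  expect_equal(perp$x_cm, perp$r_iso_cm)
  ob <- pos[pos$ray == "45deg", ]
  # distance from the isocenter equals the nominal ray distance
  expect_equal(sqrt(ob$x_cm^2 + (ob$z_cm - 100)^2), ob$r_iso_cm,
               tolerance = 1e-12)
})

test_that("synthetic generation is reproducible and noise is calibrated", {
  # noiseless generation is bit-reproducible
  expect_identical(generate_dataset(gp_grid, gp_config),
                   generate_dataset(gp_grid, gp_config))
  # seeded generation reproduces across calls
  n1 <- generate_dataset(gp_grid, gp_config, noise = noise_model(0.05, seed = 7))
  n2 <- generate_dataset(gp_grid, gp_config, noise = noise_model(0.05, seed = 7))
  expect_identical(n1, n2)
  # 5% gaussian noise on 800 records: sample relative sd within [4%, 6%]
  ratio <- n1$hd_Sv_per_Gy / gp_dataset$hd_Sv_per_Gy
  expect_gt(sd(ratio), 0.04)
  expect_lt(sd(ratio), 0.06)
  expect_true(all(n1$hd_Sv_per_Gy > 0))
  # lognormal noise is unit-mean with matching relative sd at first order
  ln <- generate_dataset(gp_grid, gp_config,
                         noise = noise_model(0.05, "lognormal", seed = 8))
  ratio_ln <- ln$hd_Sv_per_Gy / gp_dataset$hd_Sv_per_Gy
  expect_equal(mean(ratio_ln), 1, tolerance = 0.01)
  expect_gt(sd(ratio_ln), 0.04)
  expect_lt(sd(ratio_ln), 0.06)
})

test_that("a noiseless dataset closes the loop against its generating model", {
  st <- error_statistics(gp_config, gp_dataset)
  expect_identical(st$mean_pct, 0)
  expect_identical(st$max_pct, 0)
  st_oc <- error_statistics(oc_config, oc_dataset)
  expect_identical(st_oc$mean_pct, 0)
})
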