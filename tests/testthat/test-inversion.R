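test_that("relative-error cost arithmetic and scale invariance", {
  expect_equal(reflectance_cost(c(1, 2), c(1, 2)), 0)
  expect_equal(reflectance_cost(1.1 * c(3, 5, 7), c(3, 5, 7)), 0.1)
  # per-detector relative errors 0.25 and 0.2: the sum is 0.45, the cost
  # aggregates as the mean over the two fibers
  expect_equal(reflectance_cost(c(0.25, 0.08), c(0.2, 0.1)), 0.45 / 2)
  a <- 3.7
  r_sim <- c(0.31, 0.12)
  r_exp <- c(0.28, 0.13)
  expect_equal(reflectance_cost(a * r_sim, a * r_exp),
               reflectance_cost(r_sim, r_exp))
  expect_error(reflectance_cost(c(1, 2), c(1, 0)),
               class = "tiltprobe_invalid")
  expect_error(reflectance_cost(1, c(1, 2)), class = "tiltprobe_invalid")
})

test_that("grid search recovers exact fixture nodes with zero cost", {
  fx <- make_fixtures(3)
  inv <- invert_reflectance(fx$lut, fx$reflectance$r)
  expect_equal(unname(inv$estimate), unname(fx$truth))
  expect_equal(inv$cost, 0)
  # fixture LUT decreases along the mua axis
  dmu <- apply(fx$lut$values, c(1, 2, 4), diff)
  expect_lt(max(dmu), 0)
})

test_that("noise-robustness experiment behaves on the fixture LUT", {
  fx <- make_fixtures(3)
  # noiseless corruption recovers the truth at every candidate
  rob0 <- robustness_experiment(fx$lut, fx$reflectance$r, fx$truth,
                                rho_min = 0.4, noise_frac = 0,
                                n_reps = 2, seed = 1)
  expect_true(all(rob0$curve$mean_error == 0))
  expect_equal(rob0$rho_max, 0.5)
  # same seed reproduces the noisy curve exactly
  r1 <- robustness_experiment(fx$lut, fx$reflectance$r, fx$truth,
                              rho_min = 0.4, seed = 9)
  r2 <- robustness_experiment(fx$lut, fx$reflectance$r, fx$truth,
                              rho_min = 0.4, seed = 9)
  expect_identical(r1$curve, r2$curve)
})

test_that("cost-surface slices tighten as detectors are added", {
  fx <- make_fixtures(3)
  g2 <- fx$lut$grid$gamma[3]
  r <- fx$lut$values[4, 3, 2, ]
  s1 <- cost_surface_slice(fx$lut, r[1], g2, detectors = 1,
                           mask_level = 0.25)
  s3 <- cost_surface_slice(fx$lut, r, g2, mask_level = 0.25)
  expect_lt(s3$mask_area, s1$mask_area)
  # slice minimum equals the full inversion cost at that gamma
  inv <- invert_reflectance(fx$lut, r)
  expect_equal(min(cost_surface_slice(fx$lut, r, g2)$cost, na.rm = TRUE),
               inv$cost)
  expect_error(cost_surface_slice(fx$lut, r, 1.2345),
               class = "tiltprobe_invalid")
})

test_that("a small transport-built LUT supports parameter recovery", {
  grid <- lut_grid(mus_prime = c(1.5, 2, 2.5), gamma = c(1.3, 1.5, 1.7),
                   mua = seq(0, 0.6, by = 0.05))
  rho <- c(0.3, 0.4, 0.5)
  lut <- memo("tiny_lut", build_lut(grid, rho, n_photons = 1.5e5,
                                    seed = 17))
  expect_s3_class(lut, "reflectance_lut")
  expect_true(all(lut$valid))
  # reflectance decreases along the mua axis at every node
  expect_lt(max(apply(lut$values, c(1, 2, 4), diff)), 0)
  # noiseless case-1 reflectance from an independent seed: every axis
  # recovered within one grid step
  tr <- simulate_probe(case1_medium(), probe_layout(rho), n_photons = 4e5,
                       seed = 900, record_depth = FALSE)
  inv <- invert_reflectance(lut, as.numeric(reflectance(tr)))
  expect_within(inv$estimate[["mus_prime"]], 2, 0.5 + 1e-9)
  expect_within(inv$estimate[["gamma"]], 1.5, 0.2 + 1e-9)
  expect_within(inv$estimate[["mua"]], 0.2, 0.05 + 1e-9)
})

test_that("estimation error is the mean relative miss over the IOPs", {
  expect_equal(estimation_error(c(1.1, 2, 3), c(1, 2, 3)), 0.1 / 3)
  expect_equal(estimation_error(c(2, 1.9, 0.1), c(1, 1.9, 0.2)),
               mean(c(1, 0, 0.5)))
  expect_error(estimation_error(c(1, 1, 1), c(1, 0, 1)),
               class = "tiltprobe_invalid")
})
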