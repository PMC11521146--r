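test_that("launches stay on the footprint inside the acceptance cone", {
  lay <- probe_layout(0.5, tilt_deg = 40)
  L <- sample_launch(lay, 2e4)
  expect_true(all(L$z == 0))
  expect_true(all(L$x^2 + L$y^2 <= 0.05^2 + 1e-12))
  # index-matched: axis at the physical 40 deg, cone asin(0.4/1.43)
  ax <- c(sin(40 * pi / 180), 0, cos(40 * pi / 180))
  dots <- as.matrix(L[, c("ux", "uy", "uz")]) %*% ax
  expect_gte(min(dots), cos(asin(0.4 / 1.43)) - 1e-9)
  # air-coupled: axis refracts to asin(sin(40)/1.43)
  L2 <- sample_launch(lay, 2e4, index_matched = FALSE)
  ax2 <- c(sin(asin(sin(40 * pi / 180) / 1.43)), 0,
           cos(asin(sin(40 * pi / 180) / 1.43)))
  dots2 <- as.matrix(L2[, c("ux", "uy", "uz")]) %*% ax2
  expect_gte(min(dots2), cos(asin(0.4 / 1.43)) - 1e-9)
  # near-collimated fiber launches along +z
  L3 <- sample_launch(probe_layout(0.5, fiber = fiber_spec(na = 1e-3)), 1e3)
  expect_gt(min(L3$uz), 1 - 1e-5)
})

test_that("weight accounting closes and seeds are reproducible", {
  med <- case1_medium()
  lay <- probe_layout(c(0.2, 0.4))
  t1 <- simulate_probe(med, lay, n_photons = 5e4, seed = 99)
  t2 <- simulate_probe(med, lay, n_photons = 5e4, seed = 99)
  t3 <- simulate_probe(med, lay, n_photons = 5e4, seed = 100)
  expect_identical(t1$reflectance, t2$reflectance)
  expect_identical(t1$ps_w, t2$ps_w)
  expect_identical(t1$depth_w, t2$depth_w)
  expect_false(identical(t1$reflectance, t3$reflectance))
  expect_lt(abs(weight_ledger(t1)[["closure_error"]]), 1e-9)
  # with mua = 0 no weight is absorbed
  t0 <- simulate_probe(medium(2, gamma = 1.5, mua = 0), lay,
                       n_photons = 2e4, seed = 5)
  expect_equal(unname(weight_ledger(t0)[["absorbed"]]), 0)
})

test_that("reflectance decreases with separation and with absorption", {
  tl <- case1_tally()
  r <- reflectance(tl)
  expect_true(all(diff(r) < 0))
  r0 <- reflectance(simulate_probe(medium(2, gamma = 1.5, mua = 0),
                                   probe_layout(seq(0.1, 1, by = 0.1)),
                                   n_photons = 1e5, seed = 4242,
                                   record_depth = FALSE))
  expect_true(all(r0[1:5] > r[1:5]))
})

test_that("ring-overlap symmetry scoring agrees with direct detection", {
  med <- case1_medium()
  rho <- c(0.2, 0.3)
  sym <- simulate_probe(med, probe_layout(rho), n_photons = 2e5,
                        seed = 31, record_depth = FALSE)
  # a vanishing tilt forces the direct-detection path through the same
  # physics; statistics are much poorer, hence the photon imbalance
  dir <- simulate_probe(med, probe_layout(rho, tilt_deg = 1e-7),
                        n_photons = 1.2e6, seed = 32, record_depth = FALSE)
  se <- sqrt(reflectance_se(sym)^2 + reflectance_se(dir)^2)
  expect_true(all(abs(reflectance(sym) - reflectance(dir)) < 4 * se))
})

test_that("Beer-Lambert reweighting of mua = 0 paths matches direct runs", {
  med0 <- medium(2, gamma = 1.5, mua = 0)
  lay <- probe_layout(c(0.2, 0.4, 0.6))
  t0 <- simulate_probe(med0, lay, n_photons = 2e5, seed = 61,
                       record_depth = FALSE, record_paths = TRUE,
                       max_path_mm = 60)
  lmid <- (seq_len(nrow(t0$path_w)) - 0.5) * t0$path_bin_mm
  rw <- colSums(t0$path_w * exp(-0.2 * lmid)) / t0$n_photons
  td <- simulate_probe(case1_medium(), lay, n_photons = 2e5, seed = 62,
                       record_depth = FALSE)
  se <- sqrt(reflectance_se(t0)^2 + reflectance_se(td)^2)
  expect_true(all(abs(rw - reflectance(td)) < 4 * se))
})

test_that("ps counts scattering events only and normalizes", {
  tl <- case1_tally()
  ps <- ps_distribution(tl, 2)
  expect_equal(sum(ps$p), 1)
  expect_gte(min(ps$s), 1)
  expect_error(ps_distribution(synthetic_tally(matrix(0, 10, 1)), 1),
               class = "tiltprobe_invalid")
})

test_that("zv80 is the interpolated 80% depth quantile", {
  # all scattering events at 0.5 mm
  d <- matrix(0, 101, 1)
  d[51, 1] <- 10  # bin [0.50, 0.51)
  tl <- synthetic_tally(matrix(c(0, 5, 5), 3, 1), depth_w = d)
  expect_within(sampling_depth(tl, 1), 0.5, 0.011)
  # uniform event density on [0, 1] mm: 80% quantile = 0.8
  du <- matrix(0, 101, 1)
  du[1:100, 1] <- 1
  tlu <- synthetic_tally(matrix(1, 3, 1), depth_w = du)
  expect_equal(sampling_depth(tlu, 1), 0.8, tolerance = 1e-9)
  # deeper detectors sample deeper (case 1)
  tl1 <- case1_tally()
  expect_gt(sampling_depth(tl1, 6), sampling_depth(tl1, 4))
  expect_error(sampling_depth(synthetic_tally(matrix(1, 3, 1)), 1),
               class = "tiltprobe_invalid")
})

test_that("batch standard errors shrink as 1/sqrt(n)", {
  med <- case1_medium()
  lay <- probe_layout(c(0.2, 0.3, 0.4))
  s1 <- simulate_probe(med, lay, n_photons = 1e5, seed = 81,
                       record_depth = FALSE)
  s2 <- simulate_probe(med, lay, n_photons = 4e5, seed = 82,
                       record_depth = FALSE)
  ratio <- mean(reflectance_se(s1) / reflectance(s1)) /
    mean(reflectance_se(s2) / reflectance(s2))
  # expected factor 2; batch-means SE of SE is wide at 10 batches
  expect_gt(ratio, 1.25)
  expect_lt(ratio, 3.2)
  expect_error(simulate_probe(med, lay, n_photons = 1e4, n_batches = 1),
               class = "tiltprobe_invalid")
})

test_that("layout validation rejects non-physical probes", {
  expect_error(probe_layout(c(0.2, 0.25)), "overlap",
               class = "tiltprobe_invalid")
  expect_error(probe_layout(c(-0.1, 0.5)), class = "tiltprobe_invalid")
  expect_error(fiber_spec(tilt_deg = 95), class = "tiltprobe_invalid")
  expect_error(medium(-1, gamma = 1.5), class = "tiltprobe_invalid")
  expect_error(medium(2, gamma = 1.5, mua = -0.2),
               class = "tiltprobe_invalid")
})
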