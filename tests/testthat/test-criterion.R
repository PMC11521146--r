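test_that("F is the ps-weighted sum of Ws", {
  wt <- case1_ws()
  # point mass at s = 1 gives F = W1
  t1 <- synthetic_tally(matrix(c(10, 0, 0), 3, 1))
  expect_equal(unname(f_values(t1, wt)), wt$ws[1])
  # all mass beyond the table's reach gives F ~ 0
  deep <- matrix(0, 500, 1)
  deep[400, 1] <- 3
  expect_equal(unname(f_values(synthetic_tally(deep), wt)), 0)
  # mixed mass: exact weighted average
  pm <- matrix(0, 10, 1)
  pm[c(1, 5), 1] <- c(1, 3)
  expect_equal(unname(f_values(synthetic_tally(pm), wt)),
               (wt$ws[1] + 3 * wt$ws[5]) / 4)
  # raw-count variant agrees here because weights are uniform
  expect_equal(f_values(synthetic_tally(pm), wt, weighted = FALSE),
               f_values(synthetic_tally(pm), wt))
})

test_that("find_rho_min returns the smallest passing separation", {
  wt <- case1_ws()
  tl <- case1_tally()
  rho <- tl$rho_mm
  res <- find_rho_min(case1_medium(), rho, ws = wt, tally = tl)
  expect_equal(nrow(res$curve), length(rho))
  # F falls with separation: strong negative rank correlation
  expect_lt(cor(res$curve$rho_mm, res$curve$f, method = "spearman"), -0.9)
  # permissive threshold selects the first grid point
  res1 <- find_rho_min(case1_medium(), rho, threshold = 1, ws = wt,
                       tally = tl)
  expect_equal(res1$rho_min, rho[1])
  # impossible threshold reports not-found with the curve intact
  res0 <- find_rho_min(case1_medium(), rho, threshold = 0, ws = wt,
                       tally = tl)
  expect_true(is.na(res0$rho_min))
  expect_equal(nrow(res0$curve), length(rho))
})

test_that("F grows when scattering drops, absorption rises, or tilt grows", {
  wt <- case1_ws()
  f_at <- function(mus_prime, mua, tilt, n = 2e5, seed = 1234) {
    med <- medium(mus_prime, gamma = 1.5, mua = mua)
    tl <- simulate_probe(med, probe_layout(0.4, tilt_deg = tilt),
                         n_photons = n, seed = seed, record_depth = FALSE)
    unname(f_values(tl, wt))
  }
  f_base <- f_at(2, 0.2, 0)
  expect_gt(f_at(1, 0.2, 0), f_base)           # fewer scattering events
  expect_gt(f_at(2, 0.6, 0.0), f_base)         # shorter surviving paths
  expect_gt(f_at(2, 0.2, 40, n = 8e5), f_base) # shorter tilted paths
})
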