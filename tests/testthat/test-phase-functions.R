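test_that("quadrature moments match the closed-form recursions", {
  specs <- list(
    phase_hg(0.3), phase_hg(0.9), phase_hg(0.93),
    phase_mhg(1, 0.9), phase_mhg(0.9, 0.9), phase_mhg(0.5, 0.7),
    phase_mpc(1, 2), phase_mpc(0.94, 45.5), phase_mpc(0.8, 10),
    phase_mpc(1, 0.5))
  for (ph in specs) {
    gq <- numeric_moments(function(mu) phase_pdf(ph, mu), 6)
    expect_lt(max(abs(gq - phase_moments(ph, 6))), 1e-8)
  }
})

test_that("family limits and printed closed forms hold", {
  mu <- seq(-1, 1, length.out = 401)
  # isotropic HG density is 1/2 per unit cosine
  expect_equal(phase_pdf(phase_hg(0), mu), rep(0.5, length(mu)))
  # MHG with alpha = 1 reduces to pure HG
  expect_equal(phase_pdf(phase_mhg(1, 0.77), mu),
               phase_pdf(phase_hg(0.77), mu))
  # HG moments are powers of g
  expect_equal(phase_moments(phase_hg(0.9), 3), c(0.9, 0.81, 0.729))
  # pure power-of-cosines first moment N/(N+2)
  expect_equal(phase_moments(phase_mpc(1, 2), 1), 0.5)
  expect_equal(phase_moments(phase_mpc(1, 2), 2)[2], 0.1)
  # MHG(0.9, 0.9): g1 = 0.81, g2 = 0.9*0.81 + 0.4*0.1 = 0.769
  expect_equal(phase_moments(phase_mhg(0.9, 0.9), 2), c(0.81, 0.769))
  # densities stay nonnegative on a dense grid
  mu2 <- seq(-1, 1, length.out = 1e4)
  for (ph in list(phase_mhg(0.5, 0.95), phase_mpc(0.5, 100))) {
    expect_gte(min(phase_pdf(ph, mu2)), 0)
  }
})

test_that("numeric_moments validates its density", {
  expect_error(numeric_moments(function(mu) rep(1, length(mu)), 2),
               "integrates")
  expect_error(numeric_moments(function(mu) mu, 2), class =
                 "tiltprobe_invalid")
  # g0 is 1 by normalization, reflected in g_n <= 1
  g <- numeric_moments(function(mu) phase_pdf(phase_hg(0.6), mu), 8)
  expect_true(all(abs(g) <= 1))
})

test_that("moment solver round-trips targets and rejects infeasible ones", {
  targets <- list(c(0.9, 0.85), c(0.6, 0.4), c(0.9, 0.81), c(0.3, 0.2))
  for (tg in targets) {
    for (fam in c("mhg", "mpc")) {
      ph <- phase_from_moments(fam, tg[1], tg[2])
      expect_lt(max(abs(phase_moments(ph, 2) - tg)), 1e-10)
    }
    # matched pairs differ in the third moment away from the HG manifold
    g3m <- phase_moments(phase_from_moments("mhg", tg[1], tg[2]), 3)[3]
    g3p <- phase_moments(phase_from_moments("mpc", tg[1], tg[2]), 3)[3]
    expect_gt(abs(g3m - g3p), 1e-4)
  }
  # exact HG submanifold: alpha = 1 and g_hg = g1
  hg <- phase_from_moments("mhg", 0.9, 0.81)
  expect_equal(hg$alpha, 1, tolerance = 1e-9)
  expect_equal(hg$g_hg, 0.9, tolerance = 1e-9)
  # infeasible targets raise classed errors naming the constraint
  expect_error(phase_from_moments("mhg", 0.9, 0.7), "g1\\^2",
               class = "tiltprobe_infeasible")
  expect_error(phase_from_moments("mhg", 0.9, 0.97),
               class = "tiltprobe_infeasible")
  expect_error(phase_from_moments("mpc", 0.9, 0.7),
               class = "tiltprobe_infeasible")
  expect_error(phase_from_moments("mpc", 0.9, 0.97),
               class = "tiltprobe_infeasible")
})

test_that("moment_set carries gamma and enforces Legendre bounds", {
  ms <- moment_set(0.9, 0.85)
  expect_equal(ms$gamma, 1.5)
  expect_error(moment_set(1.2, 0.5), class = "tiltprobe_invalid")
  expect_error(moment_set(0.5, -0.9), class = "tiltprobe_invalid")
})

test_that("inverse-CDF samplers reproduce the analytic moments", {
  set.seed(7)
  n <- 4e5
  for (ph in list(phase_mhg(0.9, 0.9), phase_mpc(0.94, 45.5),
                  phase_hg(0.6))) {
    mu <- sample_cos_theta(ph, n)
    expect_true(all(mu >= -1 & mu <= 1))
    g12 <- phase_moments(ph, 2)
    se1 <- sd(mu) / sqrt(n)
    expect_within(mean(mu), g12[1], 4 * se1)
    p2 <- (3 * mu^2 - 1) / 2
    expect_within(mean(p2), g12[2], 4 * sd(p2) / sqrt(n))
  }
  # exponent 0 with alpha = 1 gives a flat density on [-1, 1]
  u <- sample_cos_theta(phase_mpc(1, 0), 2e5)
  expect_within(mean(u), 0, 4 / sqrt(12 * 2e5))
  expect_within(mean(u^2), 1 / 3, 0.01)
})
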