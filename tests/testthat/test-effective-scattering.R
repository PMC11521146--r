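test_that("direction composition follows the spherical cosine rule", {
  expect_equal(compose_direction(0.37, 1, 1.2), 0.37)   # no deflection
  expect_equal(compose_direction(0, 0, 0), 1)           # two right angles
  expect_equal(compose_direction(0.5, 0.5, pi), -0.5)   # 0.25 - 0.75
  expect_error(compose_direction(1.5, 0, 0), class = "tiltprobe_invalid")
  # clipped against rounding
  expect_lte(compose_direction(1 - 1e-16, 1 - 1e-16, 0), 1)
})

test_that("composed-chain moments decay as g_n^s", {
  set.seed(11)
  n <- 2e5
  for (tg in list(c(0.9, 0.85), c(0.6, 0.4))) {
    ph <- phase_from_moments("mhg", tg[1], tg[2])
    for (s in c(1, 2, 5, 10)) {
      h <- effective_pdf_mc(ph, s, n_samples = n)
      mu <- attr(h, "samples")
      se <- sd(mu) / sqrt(n)
      expect_within(mean(mu), tg[1]^s, 4 * se)
      # second raw moment: 1/3 + (2/3) g2^s
      se2 <- sd(mu^2) / sqrt(n)
      expect_within(mean(mu^2), 1 / 3 + (2 / 3) * tg[2]^s, 4 * se2)
      # histogram density integrates to one
      expect_equal(sum(h$density) * diff(h$mu[1:2]), 1, tolerance = 1e-9)
    }
  }
  # many scatterings: flat within sampling error
  h50 <- effective_pdf_mc(phase_from_moments("mhg", 0.6, 0.4), 50,
                          n_samples = 1e5, n_bins = 20)
  expect_lt(max(abs(h50$density - 0.5)), 0.03)
})

test_that("moment_decay closed forms", {
  md <- moment_decay(c(0.9, 0.7), 5)
  expect_equal(md$mean_cos, 0.59049)
  expect_equal(md$moments, c(0.9, 0.7)^5)
  # <cos^2>_s from g2 = 0.7 at s = 2: 1/3 + (2/3) 0.49 = 0.66
  expect_equal(moment_decay(c(0.9, 0.7), 2)$mean_cos2, 0.66)
  # s = 0 leaves moments at one (delta function / no scattering)
  expect_equal(moment_decay(c(0.9, 0.7), 0)$moments, c(1, 1))
  # isotropic limit 1/3
  expect_equal(moment_decay(c(0.9, 0.7), 1e6)$mean_cos2, 1 / 3)
})

test_that("Ws area and series forms agree and decay to zero", {
  for (tg in list(c(0.9, 0.85), c(0.6, 0.4), c(0.9, 0.81))) {
    for (s in c(1, 2, 3, 5, 10)) {
      wa <- ws_weight(tg[1], tg[2], s)
      wsr <- ws_weight(tg[1], tg[2], s, method = "series")
      expect_equal(attr(wa, "branch"), "area")
      expect_gt(wa, 0)
      # < 1% relative agreement between the two evaluations
      expect_lt(abs(wa - wsr) / wa, 0.01)
    }
    expect_gt(ws_weight(tg[1], tg[2], 1), ws_weight(tg[1], tg[2], 10))
  }
})

test_that("ws_table decays below tolerance and orders pairs by shape", {
  wt <- case1_ws()
  expect_s3_class(wt, "ws_table")
  expect_gt(wt$ws[1], 0)
  expect_lt(wt$ws[nrow(wt)], 1e-4)
  # flatter initial phase functions isotropize faster at every order
  for (s in c(2, 3, 5, 10)) {
    expect_lt(ws_weight(0.6, 0.4, s), ws_weight(0.9, 0.85, s))
  }
  # export as two-column delimited text
  f <- tempfile(fileext = ".tsv")
  export_ws_table(wt, f)
  back <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(back$ws, wt$ws, tolerance = 1e-12)
})
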