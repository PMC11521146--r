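#' Compose two scattering rotations
#'
#' Cosine of the direction after two successive deflections: the first by
#' polar cosine `mu1`, the second by `mu2` at relative azimuth `phi`, i.e.
#' `mu1 * mu2 + sqrt(1 - mu1^2) * sqrt(1 - mu2^2) * cos(phi)`, clipped to
#' `[-1, 1]` against rounding.
#'
#' @param mu1,mu2 Cosines in `[-1, 1]`.
#' @param phi Azimuth of the second event relative to the first, radians.
#' @return The composed cosine.
#' @export
compose_direction <- function(mu1, mu2, phi) {
  if (any(abs(mu1) > 1) || any(abs(mu2) > 1)) {
    abort_invalid("cosines must lie in [-1, 1]")
  }
  out <- mu1 * mu2 + sqrt(pmax(0, 1 - mu1^2)) * sqrt(pmax(0, 1 - mu2^2)) *
    cos(phi)
  pmin(1, pmax(-1, out))
}

#' Monte Carlo effective phase function
#'
#' Samples the direction cosine after `s` composed scattering events
#' (uniform azimuth between events) and returns a normalized histogram
#' density over the cosine — the s-scattered effective phase function.
#'
#' @inheritParams phase_pdf
#' @param s Number of scattering events (`>= 1`).
#' @param n_samples Number of composed chains.
#' @param n_bins Number of equal-width cosine bins.
#' @return A data frame with columns `mu` (bin midpoint), `density`
#'   (per unit cosine) and `count`, plus the raw samples as attribute
#'   `"samples"`.
#' @export
effective_pdf_mc <- function(phase, s, n_samples = 1e6, n_bins = 200L) {
  stopifnot(inherits(phase, "tilt_phase"), s >= 1)
  pc <- phase_code(phase)
  mu <- cpp_effective_mu(as.integer(n_samples), as.integer(s),
                         pc$fam, pc$p1, pc$p2)
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  cnt <- tabulate(findInterval(mu, breaks, rightmost.closed = TRUE),
                  nbins = n_bins)
  out <- data.frame(
    mu = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
    density = cnt / n_samples / diff(breaks)[1],
    count = cnt)
  attr(out, "samples") <- mu
  out
}

#' Legendre-moment decay under multiple scattering
#'
#' Legendre moments multiply under composition of independent rotations:
#' after `s` scattering events the n-th moment of the effective phase
#' function is `g_n^s`.  Equivalently the mean cosine decays as `g1^s` and
#' the second raw moment as
#' `<cos^2>_s = 1/3 + (2/3) * g2^s` (isotropic limit `1/3` as `s` grows).
#'
#' @param g_n Initial Legendre moments `g_1 .. g_n`.
#' @param s Number of scattering events (`>= 0`).
#' @return List with `s`, `moments` (`g_n^s`), `mean_cos` and `mean_cos2`.
#' @export
moment_decay <- function(g_n, s) {
  stopifnot(s >= 0, all(abs(g_n) <= 1))
  moments <- g_n^s
  out <- list(s = s, moments = moments, mean_cos = g_n[1]^s)
  if (length(g_n) >= 2) out$mean_cos2 <- 1 / 3 + (2 / 3) * g_n[2]^s
  out
}

#' Per-order weight Ws of the residual higher-order moments
#'
#' `Ws` quantifies how much the moments of order three and higher still
#' separate an MHG/MPC pair with matched `(g1, g2)` after `s` scattering
#' events.  The primary ("area") form solves both families at the decayed
#' moments `(g1^s, g2^s)` and integrates the absolute density difference;
#' because the first two moments match, this equals the Legendre series of
#' the difference restricted to orders `n >= 3`.  The `"series"` method
#' evaluates that expansion from the re-solved families' analytic moments
#' and serves as a consistency check on the closed-form recursions.  When a
#' decayed pair is not representable by one of the families, the weight
#' falls back to the series built from the original families' moments each
#' raised to the power `s` (branch recorded in the `"branch"` attribute).
#'
#' @param g1,g2 Moments of the single-scattering pair.
#' @param s Scattering order (`>= 1`).
#' @param method `"area"` (default) or `"series"`.
#' @param n_nodes Quadrature nodes on `[-1, 1]`.
#' @param n_terms Series truncation order.
#' @return The weight `Ws >= 0`, with attribute `"branch"` one of
#'   `"area"`, `"series"`, `"series_original"`.
#' @export
ws_weight <- function(g1, g2, s, method = c("area", "series"),
                      n_nodes = 1024L, n_terms = 384L) {
  method <- match.arg(method)
  stopifnot(s >= 1)
  d1 <- g1^s
  d2 <- g2^s
  pair <- tryCatch(
    list(mhg = solve_mhg(d1, d2), mpc = solve_mpc(d1, d2)),
    tiltprobe_infeasible = function(e) NULL)
  q <- default_quad(n_nodes)
  if (is.null(pair)) {
    # fallback: series with the original families' moments raised to s
    orig_m <- solve_mhg(g1, g2)
    orig_p <- solve_mpc(g1, g2)
    w <- ws_series_integral(phase_moments(orig_m, n_terms)^s,
                            phase_moments(orig_p, n_terms)^s, q)
    return(structure(w, branch = "series_original"))
  }
  if (method == "area") {
    w <- sum(q$w * abs(phase_pdf(pair$mhg, q$x) - phase_pdf(pair$mpc, q$x)))
    structure(w, branch = "area")
  } else {
    w <- ws_series_integral(phase_moments(pair$mhg, n_terms),
                            phase_moments(pair$mpc, n_terms), q)
    structure(w, branch = "series")
  }
}

ws_series_integral <- function(gm, gp, q) {
  n_terms <- length(gm)
  d <- (gm - gp)[3:n_terms]
  P <- legendre_matrix(n_terms, q$x)
  f <- as.numeric(crossprod(P[4:(n_terms + 1), , drop = FALSE],
                            d * (2 * (3:n_terms) + 1) / 2))
  sum(q$w * abs(f))
}

#' Table of Ws over scattering order
#'
#' Computes [ws_weight()] for `s = 1, 2, ...` until the weight drops below
#' `tol` (or `s_max` is reached).  Orders beyond the table contribute
#' negligibly to the criterion F.
#'
#' @inheritParams ws_weight
#' @param s_max Hard cap on the scattering order.
#' @param tol Stop once `Ws < tol`.
#' @return A data frame of class `ws_table` with columns `s`, `ws` and
#'   `branch`; attributes `g1`, `g2`.
#' @export
ws_table <- function(g1, g2, s_max = 300L, tol = 1e-4, n_nodes = 1024L) {
  s <- integer(0)
  ws <- numeric(0)
  branch <- character(0)
  for (si in seq_len(s_max)) {
    w <- ws_weight(g1, g2, si, n_nodes = n_nodes)
    s[si] <- si
    ws[si] <- as.numeric(w)
    branch[si] <- attr(w, "branch")
    if (ws[si] < tol) break
  }
  structure(data.frame(s = s, ws = ws, branch = branch),
            class = c("ws_table", "data.frame"), g1 = g1, g2 = g2)
}

#' Export a Ws table as delimited text
#'
#' Two tab-separated columns `s` and `ws` with a `#`-comment header noting
#' the pair moments.
#'
#' @param x A [ws_table()].
#' @param path Output file.
#' @export
export_ws_table <- function(x, path) {
  stopifnot(inherits(x, "ws_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# Ws table: g1 = %.10g, g2 = %.10g",
                     attr(x, "g1"), attr(x, "g2")), con)
  write.table(x[, c("s", "ws")], con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
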