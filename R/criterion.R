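#' Higher-order-moment criterion F
#'
#' `F = sum_s ps(s) * Ws(s)`: the weighted scattering-order distribution of
#' the photons a detector collects, weighed by the residual higher-order
#' moment influence at each order.  A small F means the collected light has
#' scattered enough times that moments above order two no longer shape the
#' reflectance, so the `(mus', gamma, mua)` description is valid; F near 1
#' flags a separation too short for the second-order approximation.
#'
#' `ps` is taken weighted by detected photon weight (consistent with a
#' weighted reflectance estimator); set `weighted = FALSE` for the
#' raw-count variant used in sensitivity checks.  Orders beyond the Ws
#' table contribute zero (the table is built down to `Ws < 1e-4`).
#'
#' @param tally A [simulate_probe()] result.
#' @param ws A [ws_table()] built from the same medium's `(g1, g2)`.
#' @param detectors Detector indices (default all).
#' @param weighted Weight ps by photon weight (default) or raw counts.
#' @return Named vector of F values in `[0, max Ws]`, one per detector.
#' @export
f_values <- function(tally, ws, detectors = NULL, weighted = TRUE) {
  stopifnot(inherits(tally, "detection_tally"), inherits(ws, "ws_table"))
  if (is.null(detectors)) detectors <- seq_along(tally$rho_mm)
  wvec <- numeric(nrow(tally$ps_w))
  wvec[ws$s[ws$s <= length(wvec)]] <- ws$ws[ws$s <= length(wvec)]
  mat <- if (weighted) tally$ps_w else tally$ps_n
  out <- vapply(detectors, function(k) {
    p <- mat[, k]
    tot <- sum(p)
    if (tot <= 0) return(NA_real_)
    sum(p * wvec) / tot
  }, numeric(1))
  setNames(out, format(tally$rho_mm[detectors]))
}

#' Minimum source-detector separation from the F criterion
#'
#' Runs one multi-detector simulation over the separation grid, computes F
#' per detector against the medium's Ws table, and returns the smallest
#' separation whose F is at or below the threshold (0.1 by the reflectance
#' error calibration: F below 10% keeps the higher-order reflectance error
#' below 10%).
#'
#' @param medium A [medium()] (its `(g1, g2)` defines the Ws table).
#' @param rho_grid Ascending separations to evaluate, mm.
#' @param tilt_deg Probe tilt, degrees.
#' @param threshold Validity threshold on F (default 0.1).
#' @param n_photons,seed,... Passed to [simulate_probe()].
#' @param fiber A [fiber_spec()].
#' @param ws Optional precomputed [ws_table()].
#' @param tally Optional precomputed tally on `rho_grid` (skips the run).
#' @return List with `rho_min` (`NA` if no grid point passes), `threshold`,
#'   `curve` (data frame `rho_mm`, `f`, `pass`), `ws`, and the `tally`.
#' @export
find_rho_min <- function(medium, rho_grid, tilt_deg = 0, threshold = 0.1,
                         n_photons = 1e6, seed = NULL,
                         fiber = fiber_spec(), ws = NULL, tally = NULL, ...) {
  if (is.unsorted(rho_grid, strictly = TRUE)) {
    abort_invalid("`rho_grid` must be strictly ascending")
  }
  if (is.null(ws)) ws <- ws_table(medium$g1, medium$g2)
  if (is.null(tally)) {
    layout <- probe_layout(rho_grid, tilt_deg = tilt_deg, fiber = fiber)
    tally <- simulate_probe(medium, layout, n_photons = n_photons,
                            seed = seed, ...)
  }
  f <- f_values(tally, ws)
  pass <- !is.na(f) & f <= threshold
  rho_min <- if (any(pass)) rho_grid[which(pass)[1]] else NA_real_
  list(rho_min = rho_min, threshold = threshold,
       curve = data.frame(rho_mm = rho_grid, f = as.numeric(f), pass = pass),
       ws = ws, tally = tally)
}
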