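#' Reflectance look-up-table grids
#'
#' `lut_grid()` returns the full-resolution axes (40 points per axis over
#' `mus' in [0.25, 3]` mm^-1, `gamma in [1, 2]`, `mua in [0, 1]` mm^-1);
#' `lut_grid_desk()` is the reduced desk-scale profile (12 x 8 x 10) used
#' throughout the examples and tests.
#'
#' @param mus_prime,gamma,mua Strictly ascending axis vectors.
#' @return A list of axes of class `lut_grid`.
#' @export
lut_grid <- function(mus_prime = seq(0.25, 3, length.out = 40),
                     gamma = seq(1, 2, length.out = 40),
                     mua = seq(0, 1, length.out = 40)) {
  for (ax in list(mus_prime, gamma, mua)) {
    if (is.unsorted(ax, strictly = TRUE)) {
      abort_invalid("LUT axes must be strictly ascending")
    }
  }
  structure(list(mus_prime = mus_prime, gamma = gamma, mua = mua),
            class = "lut_grid")
}

#' @rdname lut_grid
#' @export
lut_grid_desk <- function() {
  lut_grid(mus_prime = seq(0.25, 3, length.out = 12),
           gamma = seq(1, 2, length.out = 8),
           mua = seq(0, 1, length.out = 10))
}

#' Build a reflectance look-up table
#'
#' One transport run per `(mus', gamma)` node at `mua = 0` with per-detector
#' path-length histograms; the `mua` axis is then filled by Beer-Lambert
#' reweighting `R(mua) = sum_L w(L) exp(-mua L)`, which is exact for
#' continuous-attenuation transport (validated against direct runs in the
#' package tests).  Nodes whose `gamma` is not representable by the phase
#' family are marked invalid and excluded from the search.
#'
#' @param grid A [lut_grid()].
#' @param rho_mm Detector separations of the probe the LUT models.
#' @param tilt_deg Probe tilt, degrees.
#' @param n_photons Photons per `(mus', gamma)` node.
#' @param seed Master seed; with `common_rng = TRUE` (default) every
#'   `(mus', gamma)` node runs the same RNG stream, so step-length draws
#'   scale exactly with `1/mus` and node reflectances share their noise —
#'   the cost comparisons the grid search makes then cancel most of the
#'   Monte Carlo error (common-random-numbers variance reduction).  With
#'   `FALSE`, node seeds are derived independently.
#' @param family Phase family used to build the LUT (`"mhg"` by default, the
#'   family normally assumed when inverting measured data).
#' @param fiber,n_in,n_out,g1 Passed to [medium()]/[probe_layout()].
#' @param index_matched Fiber-face model, see [simulate_probe()].
#' @param max_path_mm Path truncation for the `mua = 0` runs, mm.
#' @param verbose Print node progress.
#' @return An object of class `reflectance_lut`: a 4-D array
#'   `[mus', gamma, mua, detector]` plus axes, validity mask, per-node
#'   standard errors at `mua = 0`, and metadata.
#' @export
build_lut <- function(grid, rho_mm, tilt_deg = 0, n_photons = 2e5,
                      seed = 1L, family = "mhg", fiber = fiber_spec(),
                      n_in = 1.43, n_out = 1.0, g1 = 0.9,
                      max_path_mm = 60, index_matched = TRUE,
                      common_rng = TRUE, verbose = FALSE) {
  stopifnot(inherits(grid, "lut_grid"))
  layout <- probe_layout(rho_mm, tilt_deg = tilt_deg, fiber = fiber)
  n1 <- length(grid$mus_prime)
  n2 <- length(grid$gamma)
  n3 <- length(grid$mua)
  nd <- length(rho_mm)
  vals <- array(NA_real_, c(n1, n2, n3, nd))
  se0 <- array(NA_real_, c(n1, n2, nd))
  valid <- matrix(FALSE, n1, n2)
  g1_used <- matrix(NA_real_, n1, n2)
  node_seed <- function(i, j) {
    if (common_rng) return(as.integer(seed))
    as.integer((as.numeric(seed) * 2147483 + i * 7919 + j * 104729) %%
                 2147483647 + 1)
  }
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      med <- tryCatch(
        medium(grid$mus_prime[i], gamma = grid$gamma[j], mua = 0,
               family = family, g1 = g1, n_in = n_in, n_out = n_out),
        tiltprobe_infeasible = function(e) NULL)
      if (is.null(med)) next
      tl <- simulate_probe(med, layout, n_photons = n_photons,
                           seed = node_seed(i, j), record_depth = FALSE,
                           record_paths = TRUE, max_path_mm = max_path_mm,
                           max_depth_mm = 12, index_matched = index_matched)
      valid[i, j] <- TRUE
      g1_used[i, j] <- med$g1
      se0[i, j, ] <- reflectance_se(tl)
      lmid <- (seq_len(nrow(tl$path_w)) - 0.5) * tl$path_bin_mm
      for (k in seq_len(n3)) {
        att <- exp(-grid$mua[k] * lmid)
        vals[i, j, k, ] <- colSums(tl$path_w * att) / n_photons
      }
      if (verbose) {
        message(sprintf("node (%d, %d): mus'=%.3g gamma=%.3g ok",
                        i, j, grid$mus_prime[i], grid$gamma[j]))
      }
    }
  }
  structure(list(values = vals, grid = grid, valid = valid,
                 g1_used = g1_used, se_mua0 = se0,
                 rho_mm = rho_mm, tilt_deg = tilt_deg, family = family,
                 index_matched = index_matched, common_rng = common_rng,
                 n_photons = n_photons, seed = seed, layout = layout),
            class = "reflectance_lut")
}

#' @export
print.reflectance_lut <- function(x, ...) {
  g <- x$grid
  cat(sprintf(paste0(
    "<reflectance_lut: %d x %d x %d nodes (%d invalid), %d detector(s),\n",
    "  tilt %g deg, %s family, %g photons/node, seed %d>\n"),
    length(g$mus_prime), length(g$gamma), length(g$mua), sum(!x$valid),
    length(x$rho_mm), x$tilt_deg, toupper(x$family), x$n_photons, x$seed))
  invisible(x)
}

#' Relative-error cost between simulated and measured reflectance
#'
#' Mean over detectors of `|r_sim - r_exp| / r_exp`.  The mean (rather than
#' the plain sum) keeps the cost comparable across detector counts; for a
#' fixed probe the two differ only by the constant number of fibers.
#'
#' @param r_sim,r_exp Per-detector reflectance vectors (same length;
#'   `r_exp > 0`).
#' @return The cost `C >= 0`.
#' @export
reflectance_cost <- function(r_sim, r_exp) {
  if (length(r_sim) != length(r_exp)) {
    abort_invalid("detector sets of `r_sim` and `r_exp` differ in length")
  }
  if (any(r_exp <= 0)) abort_invalid("all `r_exp` must be > 0")
  mean(abs(r_sim - r_exp) / r_exp)
}

#' Grid-search inversion against a look-up table
#'
#' Exhaustive search of the LUT's valid nodes for the minimum of
#' [reflectance_cost()]; ties break toward the lowest linear node index
#' (and are reported).  Nearest-node search is the primary mode, matching a
#' direct LUT search of the measured curve.
#'
#' @param lut A [build_lut()] result.
#' @param r_exp Measured/synthetic reflectance on the LUT's detectors (or
#'   the subset selected by `detectors`).
#' @param detectors Indices into the LUT detector axis (default all).
#' @return An object of class `inversion_result`: `estimate` (named vector
#'   `mus_prime`, `gamma`, `mua`), `cost`, `index`, `n_ties`.
#' @export
invert_reflectance <- function(lut, r_exp, detectors = NULL) {
  stopifnot(inherits(lut, "reflectance_lut"))
  if (is.null(detectors)) detectors <- seq_along(lut$rho_mm)
  if (length(r_exp) != length(detectors)) {
    abort_invalid("`r_exp` length must match the selected detectors")
  }
  if (any(r_exp <= 0)) abort_invalid("all `r_exp` must be > 0")
  g <- lut$grid
  n1 <- length(g$mus_prime); n2 <- length(g$gamma); n3 <- length(g$mua)
  v <- lut$values[, , , detectors, drop = FALSE]
  nd <- length(detectors)
  # cost over all nodes: mean_k |v - r| / r
  cost <- array(0, c(n1, n2, n3))
  for (k in seq_len(nd)) {
    cost <- cost + abs(v[, , , k] - r_exp[k]) / r_exp[k]
  }
  cost <- cost / nd
  cost[!array(rep(lut$valid, n3), c(n1, n2, n3))] <- Inf
  best <- min(cost)
  if (!is.finite(best)) abort_invalid("all LUT nodes are invalid")
  idx <- which(cost == best)
  ij <- arrayInd(idx[1], dim(cost))
  structure(list(
    estimate = c(mus_prime = g$mus_prime[ij[1]], gamma = g$gamma[ij[2]],
                 mua = g$mua[ij[3]]),
    cost = best, index = as.integer(ij), n_ties = length(idx),
    detectors = detectors),
    class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf(
    "<inversion_result: mus' = %.4g mm^-1, gamma = %.4g, mua = %.4g mm^-1; C = %.4g%s>\n",
    x$estimate[["mus_prime"]], x$estimate[["gamma"]], x$estimate[["mua"]],
    x$cost, if (x$n_ties > 1) sprintf(" (%d ties)", x$n_ties) else ""))
  invisible(x)
}

#' Mean relative estimation error over the three optical properties
#'
#' `mean(|estimate - truth| / truth)` over `mus'`, `gamma` and `mua` — the
#' symmetric, dimensionless error used to judge inversion robustness.
#'
#' @param estimate,truth Named or positional vectors
#'   `(mus_prime, gamma, mua)`.
#' @return Scalar error.
#' @export
estimation_error <- function(estimate, truth) {
  estimate <- as.numeric(estimate)
  truth <- as.numeric(truth)
  if (any(truth == 0)) abort_invalid("truth values must be nonzero")
  mean(abs(estimate - truth) / abs(truth))
}

#' Noise-robustness experiment: choosing the maximum separation
#'
#' For each candidate maximum separation, corrupts the truth reflectance
#' with independent multiplicative Gaussian noise (`sigma = noise_frac *
#' R`; negative draws resampled), inverts the detectors between `rho_min`
#' and the candidate against the LUT, and averages [estimation_error()]
#' over replicates.  The selected `rho_max` is the smallest candidate whose
#' mean error is at or below `error_tol` (10% by default, matching the
#' acceptability threshold used with 10% measurement noise).
#'
#' @param lut A [build_lut()] whose detectors cover the candidates.
#' @param r_truth Noise-free truth reflectance on the LUT's detector set.
#' @param truth True `(mus_prime, gamma, mua)` used to score the error.
#' @param rho_min Minimum separation (fixed by the F criterion), mm.
#' @param rho_max_grid Candidate maximum separations, mm (subset of the
#'   LUT's detectors above `rho_min`).
#' @param noise_frac Relative noise level (default 0.10).
#' @param n_reps Replicates per candidate (default 10).
#' @param seed Seed for the noise stream.
#' @param error_tol Acceptable mean estimation error (default 0.10).
#' @return List with `rho_max` (`NA` if no candidate passes), `curve`
#'   (data frame `rho_max_mm`, `mean_error`, `se`), and the settings.
#' @export
robustness_experiment <- function(lut, r_truth, truth, rho_min,
                                  rho_max_grid = NULL, noise_frac = 0.10,
                                  n_reps = 10L, seed = NULL,
                                  error_tol = 0.10) {
  stopifnot(inherits(lut, "reflectance_lut"))
  if (length(r_truth) != length(lut$rho_mm)) {
    abort_invalid("`r_truth` must cover the LUT's detector set")
  }
  if (is.null(rho_max_grid)) {
    rho_max_grid <- lut$rho_mm[lut$rho_mm > rho_min + 1e-9]
  }
  if (!is.null(seed)) set.seed(seed)
  err <- matrix(NA_real_, n_reps, length(rho_max_grid))
  for (r in seq_len(n_reps)) {
    noisy <- vapply(r_truth, function(x) {
      repeat {
        y <- x * (1 + noise_frac * rnorm(1))
        if (y > 0) return(y)
      }
    }, numeric(1))
    for (ci in seq_along(rho_max_grid)) {
      det <- which(lut$rho_mm >= rho_min - 1e-9 &
                   lut$rho_mm <= rho_max_grid[ci] + 1e-9)
      inv <- invert_reflectance(lut, noisy[det], detectors = det)
      err[r, ci] <- estimation_error(inv$estimate, truth)
    }
  }
  mean_error <- colMeans(err)
  se <- apply(err, 2, sd) / sqrt(n_reps)
  pass <- mean_error <= error_tol
  list(rho_max = if (any(pass)) rho_max_grid[which(pass)[1]] else NA_real_,
       curve = data.frame(rho_max_mm = rho_max_grid,
                          mean_error = mean_error, se = se),
       noise_frac = noise_frac, n_reps = n_reps, error_tol = error_tol,
       rho_min = rho_min)
}

#' Cost-surface slice for diagnostics
#'
#' The inversion cost over the `(mus', mua)` plane at a fixed on-grid
#' `gamma`, together with the mask of nodes whose cost is below
#' `mask_level` (0.1 by default): the low-cost valley of a single-fiber
#' inversion versus the tighter basin of a multi-fiber one.
#'
#' @inheritParams invert_reflectance
#' @param gamma A value on the LUT's gamma axis.
#' @param mask_level Contour level for the low-cost mask.
#' @return List with `cost` (matrix `mus' x mua`), `mask`, `mask_area`
#'   (fraction of valid nodes below the level), and the axes.
#' @export
cost_surface_slice <- function(lut, r_exp, gamma, detectors = NULL,
                               mask_level = 0.1) {
  stopifnot(inherits(lut, "reflectance_lut"))
  j <- which(abs(lut$grid$gamma - gamma) < 1e-9)
  if (length(j) != 1) abort_invalid("`gamma` must be a LUT grid value")
  if (is.null(detectors)) detectors <- seq_along(lut$rho_mm)
  g <- lut$grid
  n1 <- length(g$mus_prime); n3 <- length(g$mua)
  cost <- matrix(0, n1, n3)
  for (k in seq_along(detectors)) {
    cost <- cost + abs(lut$values[, j, , detectors[k]] - r_exp[k]) / r_exp[k]
  }
  cost <- cost / length(detectors)
  cost[!lut$valid[, j], ] <- NA
  mask <- !is.na(cost) & cost < mask_level
  list(cost = cost, mask = mask,
       mask_area = sum(mask) / sum(!is.na(cost)),
       mus_prime = g$mus_prime, mua = g$mua, gamma = g$gamma[j])
}
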