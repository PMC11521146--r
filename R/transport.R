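#' Turbid medium specification
#'
#' A homogeneous semi-infinite medium described by the reduced scattering
#' coefficient `mus_prime` (mm^-1), the subdiffusive parameter `gamma`, and
#' the absorption coefficient `mua` (mm^-1).  The full scattering
#' coefficient and the phase function are resolved from `(mus_prime, gamma)`
#' by fixing the anisotropy `g1` (default 0.9, a common soft-tissue value):
#' `g2 = 1 - gamma * (1 - g1)` and `mus = mus_prime / (1 - g1)`.  If the
#' pair `(g1, g2)` is not representable by the requested family, `g1` is
#' stepped by 0.05 within `[0.6, 0.95]` and the feasible value nearest the
#' preferred one is used (recorded in the result); if none works the
#' infeasibility error propagates.
#'
#' @param mus_prime Reduced scattering coefficient, mm^-1 (`> 0`).
#' @param gamma Subdiffusive parameter `(1 - g2)/(1 - g1)`.
#' @param mua Absorption coefficient, mm^-1 (`>= 0`).
#' @param family Phase-function family, `"mhg"` or `"mpc"`.
#' @param g1 Preferred anisotropy used to disaggregate `mus_prime`.
#' @param phase Optionally a ready-made [phase_hg()]-style object; then
#'   `gamma`/`family`/`g1` are ignored and moments come from the object.
#' @param n_in Tissue refractive index (default 1.43).
#' @param n_out External refractive index (default 1.0, air).
#' @return An object of class `tilt_medium`.
#' @examples
#' medium(mus_prime = 2, gamma = 1.5, mua = 0.2)
#' @export
medium <- function(mus_prime, gamma = NULL, mua = 0, family = "mhg",
                   g1 = 0.9, phase = NULL, n_in = 1.43, n_out = 1.0) {
  if (mus_prime <= 0) abort_invalid("`mus_prime` must be > 0")
  if (mua < 0) abort_invalid("`mua` must be >= 0")
  if (n_in < 1) abort_invalid("`n_in` must be >= 1")
  if (is.null(phase)) {
    if (is.null(gamma)) abort_invalid("supply `gamma` or a `phase` object")
    res <- resolve_phase(family, gamma, g1)
    phase <- res$phase
    g1_used <- res$g1
  } else {
    stopifnot(inherits(phase, "tilt_phase"))
    g1_used <- phase_moments(phase, 1)
  }
  g12 <- phase_moments(phase, 2)
  structure(list(
    mus_prime = mus_prime, mua = mua,
    mus = mus_prime / (1 - g12[1]),
    g1 = g12[1], g2 = g12[2],
    gamma = (1 - g12[2]) / (1 - g12[1]),
    phase = phase, n_in = n_in, n_out = n_out,
    g1_preferred = g1, g1_used = g1_used),
    class = "tilt_medium")
}

# solve the (gamma, g1) -> family parameters map with the +/- 0.05 fallback
resolve_phase <- function(family, gamma, g1_pref) {
  steps <- unique(pmin(0.95, pmax(0.6, g1_pref + 0.05 *
    c(0, rep(seq_len(7), each = 2) * c(-1, 1)))))
  last_err <- NULL
  for (g1 in steps) {
    g2 <- 1 - gamma * (1 - g1)
    ph <- tryCatch(phase_from_moments(family, g1, g2),
                   tiltprobe_infeasible = function(e) e)
    if (inherits(ph, "tilt_phase")) return(list(phase = ph, g1 = g1))
    last_err <- ph
  }
  rlang::abort(sprintf(
    "gamma = %.4g is not representable by %s for any g1 in [0.6, 0.95]",
    gamma, toupper(family)), class = c("tiltprobe_infeasible",
                                       "tiltprobe_error"))
}

#' @export
print.tilt_medium <- function(x, ...) {
  cat(sprintf(paste0(
    "<tilt_medium: mus' = %.3g mm^-1, gamma = %.3g, mua = %.3g mm^-1\n",
    "  mus = %.4g mm^-1, g1 = %.3f, g2 = %.3f, phase = %s, n = %.2f>\n"),
    x$mus_prime, x$gamma, x$mua, x$mus, x$g1, x$g2,
    toupper(x$phase$family), x$n_in))
  invisible(x)
}

#' Fiber specification
#'
#' @param diameter_mm Core diameter, mm.
#' @param na Numerical aperture (dimensionless).
#' @param tilt_deg Tilt from the surface normal, degrees, `0 <= tilt < 90`.
#' @return An object of class `fiber_spec`.
#' @export
fiber_spec <- function(diameter_mm = 0.1, na = 0.4, tilt_deg = 0) {
  if (diameter_mm <= 0) abort_invalid("`diameter_mm` must be > 0")
  if (tilt_deg < 0 || tilt_deg >= 90) {
    abort_invalid("`tilt_deg` must lie in [0, 90)")
  }
  if (na <= 0) abort_invalid("`na` must be > 0")
  structure(list(diameter_mm = diameter_mm, na = na, tilt_deg = tilt_deg),
            class = "fiber_spec")
}

#' Probe layout: one source fiber and a set of detector fibers
#'
#' The source footprint is centred at the origin and detectors lie along
#' `+x` at the source-detector separations `rho_mm`.  Source and detectors
#' share the fiber spec and are tilted by the same angle in opposite
#' directions in the source-detector plane (tilted toward each other), the
#' standard tilted-probe arrangement.  Footprints must not overlap.
#'
#' @param rho_mm Detector separations, mm (all `> 0`, ascending).
#' @param tilt_deg Common tilt magnitude, degrees.
#' @param fiber A [fiber_spec()] shared by source and detectors.
#' @return An object of class `probe_layout`.
#' @examples
#' probe_layout(seq(0.1, 1, by = 0.1), tilt_deg = 40)
#' @export
probe_layout <- function(rho_mm, tilt_deg = 0, fiber = fiber_spec()) {
  stopifnot(inherits(fiber, "fiber_spec"))
  if (any(rho_mm <= 0)) abort_invalid("all `rho_mm` must be > 0")
  if (is.unsorted(rho_mm, strictly = TRUE)) {
    abort_invalid("`rho_mm` must be strictly ascending")
  }
  d <- fiber$diameter_mm
  if (any(diff(c(0, rho_mm)) < d - 1e-12)) {
    abort_invalid("fiber footprints overlap: separations must exceed the diameter")
  }
  fiber$tilt_deg <- tilt_deg
  structure(list(rho_mm = as.numeric(rho_mm), tilt_deg = tilt_deg,
                 fiber = fiber), class = "probe_layout")
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf(
    "<probe_layout: %d detector(s) at %s mm, tilt %g deg, d = %g mm, NA = %g>\n",
    length(x$rho_mm), paste(signif(x$rho_mm, 3), collapse = ", "),
    x$tilt_deg, x$fiber$diameter_mm, x$fiber$na))
  invisible(x)
}

#' Sample photon launches (geometry diagnostic)
#'
#' Positions uniform over the source footprint, directions uniform in solid
#' angle within the in-tissue acceptance cone `asin(NA/n_in)` about the
#' refracted source axis.
#'
#' @param layout A [probe_layout()].
#' @param n Number of launches.
#' @param n_in Tissue refractive index.
#' @param index_matched As in [simulate_probe()]: `TRUE` keeps the physical
#'   tilt as the in-tissue axis, `FALSE` refracts it at the surface.
#' @return Data frame with columns `x, y, z, ux, uy, uz`.
#' @export
sample_launch <- function(layout, n, n_in = 1.43, index_matched = TRUE) {
  m <- cpp_sample_launch(as.integer(n), layout$tilt_deg * pi / 180,
                         layout$fiber$diameter_mm / 2, layout$fiber$na, n_in,
                         index_matched)
  setNames(as.data.frame(m), c("x", "y", "z", "ux", "uy", "uz"))
}

#' Run the photon transport simulation
#'
#' Propagates photon packets through the medium: exponential step lengths
#' (`-log(xi)/mus`), deflections sampled from the medium's phase function
#' with uniform azimuth, continuous Beer-Lambert weight attenuation
#' `exp(-mua * L)` (no discrete absorption events), unpolarized Fresnel
#' reflection/refraction at every surface crossing, and Russian roulette
#' below weight `1e-4` with survival probability 0.1.  Exiting photons are
#' tested against each detector footprint and acceptance cone; for
#' perpendicular probes the azimuthal symmetry is exploited by scoring each
#' accepted exiting photon into every detector with its exit-ring overlap
#' fraction, which greatly reduces variance without bias.
#'
#' Photons are terminated once their path length exceeds `max_path_mm` or
#' their depth exceeds `max_depth_mm`; both truncate only trajectories whose
#' detection probability is negligible at the sub-millimetre separations the
#' probe uses.
#'
#' @param medium A [medium()].
#' @param layout A [probe_layout()].
#' @param n_photons Number of photon packets.
#' @param seed Integer seed for the transport RNG stream; if `NULL`, drawn
#'   from R's RNG.  Identical seeds give byte-identical tallies.
#' @param n_batches Number of batches for the batch-means standard error
#'   (`>= 2`; 10 by default).
#' @param record_depth Record the depth histogram of the scattering events
#'   of detected photons (needed for [sampling_depth()]).
#' @param record_paths Record per-detector path-length histograms (needed
#'   for the Beer-Lambert `mua` reweighting used by [build_lut()]).
#' @param max_path_mm,max_depth_mm Truncation bounds, mm.
#' @param index_matched Treat the fiber faces as index-matched to the
#'   tissue (contact probe, default `TRUE`): the source axis keeps its
#'   physical tilt inside the tissue and detection is decided on the
#'   internal direction within `asin(NA/n_in)` of the internal detector
#'   axis, before any Fresnel event.  With `FALSE` the faces behave like
#'   the surrounding air boundary: the launch axis refracts at the surface
#'   and acceptance is tested on the refracted external direction within
#'   `asin(NA/n_out)`.
#' @param depth_bin_mm Depth histogram bin width, mm.
#' @param path_bin_mm Path-length histogram bin width, mm.
#' @param s_cap Scattering-order histogram cap (overflow pooled).
#' @return An object of class `detection_tally`.
#' @export
simulate_probe <- function(medium, layout, n_photons = 1e6, seed = NULL,
                           n_batches = 10L, record_depth = TRUE,
                           record_paths = FALSE, index_matched = TRUE,
                           max_path_mm = 100, max_depth_mm = 12,
                           depth_bin_mm = 0.01, path_bin_mm = 0.02,
                           s_cap = 3000L) {
  stopifnot(inherits(medium, "tilt_medium"), inherits(layout, "probe_layout"))
  if (n_photons < 1) abort_invalid("`n_photons` must be >= 1")
  if (n_batches < 2) abort_invalid("`n_batches` must be >= 2")
  if (layout$fiber$na >= min(medium$n_in, medium$n_out)) {
    abort_invalid("numerical aperture must be below both refractive indices")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  seed <- as.integer(seed)
  pc <- phase_code(medium$phase)
  res <- cpp_transport(
    n_photons, as.integer(n_batches),
    medium$mus, medium$mua, pc$fam, pc$p1, pc$p2,
    medium$n_in, medium$n_out,
    layout$tilt_deg * pi / 180, layout$fiber$diameter_mm / 2,
    layout$fiber$na, layout$rho_mm,
    max_path_mm, max_depth_mm, depth_bin_mm, max_depth_mm,
    as.integer(s_cap), record_paths, record_depth,
    path_bin_mm, abs(seed), 2654435769, index_matched)
  structure(list(
    reflectance = res$reflectance_w / n_photons,
    batch_w = res$batch_w,
    ps_w = res$ps_w,
    ps_n = res$ps_n,
    depth_w = if (record_depth) res$depth_w else NULL,
    path_w = if (record_paths) res$path_w else NULL,
    n_detected = res$n_detected,
    ledger = res$ledger,
    rho_mm = layout$rho_mm,
    tilt_deg = layout$tilt_deg,
    n_photons = n_photons, n_batches = n_batches, seed = seed,
    depth_bin_mm = depth_bin_mm, path_bin_mm = path_bin_mm,
    index_matched = index_matched,
    medium = medium, layout = layout),
    class = "detection_tally")
}

#' @export
print.detection_tally <- function(x, ...) {
  cat(sprintf("<detection_tally: %g photons, tilt %g deg, seed %d>\n",
              x$n_photons, x$tilt_deg, x$seed))
  df <- data.frame(rho_mm = x$rho_mm,
                   reflectance = signif(x$reflectance, 4),
                   rel_se = signif(reflectance_se(x) /
                                     pmax(x$reflectance, 1e-300), 2),
                   n_detected = round(x$n_detected, 1))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Accessors for a detection tally
#'
#' `reflectance()` returns the collected weight fraction per detector;
#' `reflectance_se()` its batch-means standard error;
#' `ps_distribution()` the normalized weighted distribution of the number
#' of scattering events of the photons collected by one detector.
#'
#' @param tally A [simulate_probe()] result.
#' @param detector Detector index (along `rho_mm`).
#' @return `reflectance`/`reflectance_se`: numeric per detector;
#'   `ps_distribution`: data frame `(s, p)` with `sum(p) = 1`.
#' @export
reflectance <- function(tally) {
  stopifnot(inherits(tally, "detection_tally"))
  setNames(tally$reflectance, format(tally$rho_mm))
}

#' @rdname reflectance
#' @export
reflectance_se <- function(tally) {
  stopifnot(inherits(tally, "detection_tally"))
  per_batch <- tally$n_photons / tally$n_batches
  br <- tally$batch_w / per_batch
  se <- apply(br, 2, sd) / sqrt(tally$n_batches)
  setNames(se, format(tally$rho_mm))
}

#' @rdname reflectance
#' @export
ps_distribution <- function(tally, detector) {
  stopifnot(inherits(tally, "detection_tally"))
  w <- tally$ps_w[, detector]
  if (sum(w) <= 0) abort_invalid("no photons detected: ps undefined")
  keep <- which(w > 0)
  data.frame(s = keep, p = w[keep] / sum(w))
}

#' Sampling depth zv80
#'
#' The depth above which a fraction `prob` (default 80%) of the weighted
#' scattering events of the photons collected by a detector take place,
#' with linear interpolation inside the containing histogram bin.
#'
#' @inheritParams reflectance
#' @param prob Quantile of the scattering-event mass (default 0.8).
#' @return Depth in mm.
#' @export
sampling_depth <- function(tally, detector, prob = 0.8) {
  stopifnot(inherits(tally, "detection_tally"))
  if (is.null(tally$depth_w)) {
    abort_invalid("tally was run with record_depth = FALSE")
  }
  w <- tally$depth_w[, detector]
  if (sum(w) <= 0) abort_invalid("no scattering events recorded for this detector")
  nb <- length(w) - 1  # last bin is overflow
  breaks <- c(seq(0, nb * tally$depth_bin_mm, by = tally$depth_bin_mm),
              Inf)
  weighted_quantile_hist(breaks, w, prob)
}

#' Weight-conservation ledger
#'
#' Per-run accounting of launched weight: detected + escaped + absorbed +
#' truncated + roulette-terminated minus the roulette boost equals the
#' number of launched photons exactly (the roulette game is unbiased in
#' expectation and the ledger tracks its boosts explicitly).
#'
#' @inheritParams reflectance
#' @return Named numeric vector with the closure residual in
#'   `closure_error` (relative).
#' @export
weight_ledger <- function(tally) {
  stopifnot(inherits(tally, "detection_tally"))
  led <- tally$ledger
  closure <- (led[["detected"]] + led[["escaped"]] + led[["absorbed"]] +
              led[["killed"]] + led[["roulette_killed"]] -
              led[["roulette_gain"]]) / tally$n_photons - 1
  c(led, closure_error = closure)
}
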