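#' Reference optical-property cases
#'
#' `case_typical()` is a representative soft-tissue visible-range case
#' (`mus' = 2` mm^-1, `gamma = 1.5`, `mua = 0.2` mm^-1); `case_limiting()`
#' is the realistic worst case used as the default probe-design input — the
#' combination of low scattering and appreciable absorption that demands the
#' largest minimum separation (`mus' = 1` mm^-1, `gamma = 1.9`,
#' `mua = 0.2` mm^-1).
#'
#' @return Named list `(mus_prime, gamma, mua)`.
#' @export
case_typical <- function() list(mus_prime = 2, gamma = 1.5, mua = 0.2)

#' @rdname case_typical
#' @export
case_limiting <- function() list(mus_prime = 1, gamma = 1.9, mua = 0.2)

#' Three-step probe-design workflow
#'
#' For a medium and tilt angle: (1) find the minimum separation `rho_min`
#' from the criterion F on the separation grid; (2) find the maximum
#' separation `rho_max` from the noise-robustness of the LUT inversion with
#' detectors every grid step from `rho_min`; (3) evaluate the sampling
#' depth zv80 at `rho_max`.  Step 2 can be replaced by a fixed
#' `rho_max_offset` (mm added to `rho_min`), e.g. the offset found for
#' another tilt of the same probe, since the offset is nearly
#' tilt-independent.
#'
#' A not-found outcome in either step yields a partial report with the
#' corresponding field `NA` and the diagnostic curves still attached.
#'
#' @param props Named list `(mus_prime, gamma, mua)`; see [case_limiting()].
#' @param tilt_deg Probe tilt, degrees.
#' @param rho_grid Separation grid, mm (default 0.1-2.0 by 0.1).
#' @param n_photons Photons for the criterion run.
#' @param lut Optional prebuilt [build_lut()] on this geometry; required
#'   for step 2 unless `rho_max_offset` is given.
#' @param rho_max_offset Optional fixed offset, mm (skips step 2).
#' @param threshold F-criterion threshold (default 0.1).
#' @param noise_frac,n_reps,error_tol Passed to [robustness_experiment()].
#' @param seed Master seed; sub-seeds are derived per step.
#' @param fiber A [fiber_spec()].
#' @return An object of class `design_report`.
#' @examples
#' \donttest{
#' rep <- run_design(case_limiting(), tilt_deg = 0,
#'                   rho_grid = seq(0.1, 1, by = 0.1),
#'                   n_photons = 2e5, rho_max_offset = 0.5, seed = 7)
#' rep
#' }
#' @export
run_design <- function(props, tilt_deg = 0,
                       rho_grid = seq(0.1, 2.0, by = 0.1),
                       n_photons = 1e6, lut = NULL, rho_max_offset = NULL,
                       threshold = 0.1, noise_frac = 0.10, n_reps = 10L,
                       error_tol = 0.10, seed = NULL, fiber = fiber_spec()) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  seed <- as.integer(seed)
  sub_seed <- function(k) {
    as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647 + 1)
  }
  med <- medium(props$mus_prime, gamma = props$gamma, mua = props$mua)

  # step 1: minimum separation from the F criterion
  step1 <- find_rho_min(med, rho_grid, tilt_deg = tilt_deg,
                        threshold = threshold, n_photons = n_photons,
                        seed = sub_seed(1), fiber = fiber)
  rho_min <- step1$rho_min

  # step 2: maximum separation from inversion robustness under noise
  rho_max <- NA_real_
  error_curve <- NULL
  if (!is.na(rho_min)) {
    if (!is.null(rho_max_offset)) {
      rho_max <- rho_min + rho_max_offset
    } else if (!is.null(lut)) {
      det <- match_detectors(lut$rho_mm, rho_grid)
      rob <- robustness_experiment(
        lut, reflectance(step1$tally)[det], unlist(props), rho_min,
        noise_frac = noise_frac, n_reps = n_reps, seed = sub_seed(2),
        error_tol = error_tol)
      rho_max <- rob$rho_max
      error_curve <- rob$curve
    }
  }

  # step 3: sampling depth at the maximum separation
  zv80 <- NA_real_
  if (!is.na(rho_max)) {
    k <- which(abs(rho_grid - rho_max) < 1e-9)
    if (length(k) == 1) {
      zv80 <- sampling_depth(step1$tally, k)
    }
  }

  structure(list(
    scenario = list(props = props, tilt_deg = tilt_deg, fiber = fiber),
    rho_min = rho_min, rho_max = rho_max, zv80 = zv80,
    f_curve = step1$curve, error_curve = error_curve,
    threshold = threshold, noise_frac = noise_frac,
    seed = seed, n_photons = n_photons,
    config_hash = rlang::hash(list(props, tilt_deg, rho_grid, n_photons,
                                   threshold, noise_frac, n_reps, seed))),
    class = "design_report")
}

# map LUT detector separations onto the design grid (exact within 1e-9)
match_detectors <- function(lut_rho, rho_grid) {
  idx <- vapply(lut_rho, function(r) {
    k <- which(abs(rho_grid - r) < 1e-9)
    if (length(k) != 1) {
      abort_invalid("LUT detectors must be a subset of the design grid")
    }
    k
  }, integer(1))
  idx
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<design_report: tilt %g deg, mus' = %g, gamma = %g, mua = %g>\n",
    "  rho_min = %s mm, rho_max = %s mm, zv80 = %s mm\n",
    "  (seed %d, %g photons, config %s)\n"),
    x$scenario$tilt_deg, x$scenario$props$mus_prime,
    x$scenario$props$gamma, x$scenario$props$mua,
    format(x$rho_min), format(x$rho_max),
    if (is.na(x$zv80)) "NA" else sprintf("%.3f", x$zv80),
    x$seed, x$n_photons, substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Write a design report as structured text (JSON)
#'
#' Curves are embedded as arrays; the provenance block (seed, photon
#' budget, config hash) is carried along.
#'
#' @param x A [run_design()] report.
#' @param path Output file.
#' @export
write_design_report <- function(x, path) {
  stopifnot(inherits(x, "design_report"))
  jsonlite::write_json(
    list(scenario = x$scenario[c("props", "tilt_deg")],
         rho_min_mm = x$rho_min, rho_max_mm = x$rho_max, zv80_mm = x$zv80,
         threshold = x$threshold, noise_frac = x$noise_frac,
         f_curve = x$f_curve, error_curve = x$error_curve,
         seed = x$seed, n_photons = x$n_photons,
         config_hash = x$config_hash),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
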