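#' Run configuration files
#'
#' Runs are described by a YAML file with blocks `medium` (`mus_prime`,
#' `gamma`, `mua`, optional `family`, `g1`, `n_in`, `n_out`), `layout`
#' (`rho_mm`, `tilt_deg`, `diameter_mm`, `na`), `budget` (`n_photons`,
#' `n_batches`), `seed` and `profile` (`"desk"` or `"production"`).  Unknown
#' keys, missing required keys and non-physical values are all reported
#' together in one validation error.
#'
#' @param path File to read or write.
#' @return `load_config()`: a validated list of class `run_config` with a
#'   `config_hash` attribute; `save_config()` writes YAML and returns the
#'   path.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("config `%s` not found", path))
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg A config list (e.g. from [default_config()]).
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname load_config
#' @export
default_config <- function() {
  validate_config(list(
    medium = c(case_typical(), list(family = "mhg", g1 = 0.9,
                                    n_in = 1.43, n_out = 1.0)),
    layout = list(rho_mm = seq(0.1, 1.0, by = 0.1), tilt_deg = 0,
                  diameter_mm = 0.1, na = 0.4),
    budget = list(n_photons = 1e6, n_batches = 10),
    seed = 1L, profile = "desk"))
}

validate_config <- function(cfg) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  known_top <- c("medium", "layout", "budget", "seed", "profile")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra)) note(sprintf("unknown top-level key(s): %s",
                                  paste(extra, collapse = ", ")))
  for (blk in c("medium", "layout", "budget")) {
    if (is.null(cfg[[blk]])) note(sprintf("missing block `%s`", blk))
  }
  m <- cfg$medium
  if (!is.null(m)) {
    known <- c("mus_prime", "gamma", "mua", "family", "g1", "n_in", "n_out")
    extra <- setdiff(names(m), known)
    if (length(extra)) note(sprintf("unknown medium key(s): %s",
                                    paste(extra, collapse = ", ")))
    if (is.null(m$mus_prime) || m$mus_prime <= 0) {
      note("medium.mus_prime (mm^-1) must be > 0")
    }
    if (is.null(m$mua) || m$mua < 0) note("medium.mua (mm^-1) must be >= 0")
    if (is.null(m$gamma) || m$gamma < 1 || m$gamma > 2.5) {
      note("medium.gamma must lie in [1, 2.5]")
    }
  }
  l <- cfg$layout
  if (!is.null(l)) {
    known <- c("rho_mm", "tilt_deg", "diameter_mm", "na")
    extra <- setdiff(names(l), known)
    if (length(extra)) note(sprintf("unknown layout key(s): %s",
                                    paste(extra, collapse = ", ")))
    if (is.null(l$rho_mm) || any(l$rho_mm <= 0)) {
      note("layout.rho_mm (mm) must all be > 0")
    }
    if (!is.null(l$tilt_deg) && (l$tilt_deg < 0 || l$tilt_deg >= 90)) {
      note("layout.tilt_deg must lie in [0, 90)")
    }
  }
  b <- cfg$budget
  if (!is.null(b)) {
    if (is.null(b$n_photons) || b$n_photons < 1) {
      note("budget.n_photons must be >= 1")
    }
  }
  if (!is.null(cfg$profile) &&
      !cfg$profile %in% c("desk", "production")) {
    note("profile must be 'desk' or 'production'")
  }
  if (length(problems)) {
    abort_invalid(paste0("invalid configuration:\n- ",
                         paste(problems, collapse = "\n- ")))
  }
  structure(cfg, class = "run_config",
            config_hash = rlang::hash(yaml::as.yaml(unclass(cfg))))
}

#' Stable hash of a configuration
#'
#' @param cfg A `run_config` (or any list).
#' @return Character hash; identical configurations hash identically.
#' @export
config_hash <- function(cfg) {
  h <- attr(cfg, "config_hash")
  if (is.null(h)) h <- rlang::hash(yaml::as.yaml(unclass(cfg)))
  h
}

#' Deterministic fixtures for criterion and inversion machinery
#'
#' Small, seed-reproducible objects that exercise the criterion and
#' inversion code paths without transport runs: a scattering-order
#' distribution, a three-detector reflectance curve, and a synthetic
#' 6 x 6 x 6 mini-LUT whose values come from a smooth closed-form
#' reflectance surrogate `a * mus'^1.2 * (1 + 0.25 (gamma - 1.5)) *
#' exp(-sqrt(3 mua (mua + mus')) rho) / (rho + 0.2)^2` — monotone
#' decreasing along the `mua` axis and varying along all three, but not a
#' transport solution (it stands in for one only where the tests need LUT
#' mechanics, not physics).
#'
#' @param seed Integer seed.
#' @return List with `ps` (data frame `s`, `p`), `reflectance` (data frame
#'   `rho_mm`, `r`), `lut` (a `reflectance_lut`), and `truth` (the node the
#'   reflectance curve was generated from, with noise-free values).
#' @export
make_fixtures <- function(seed = 1L) {
  set.seed(seed)
  s <- 1:60
  p <- stats::dnbinom(s - 1, size = 3, mu = 12)
  ps <- data.frame(s = s, p = p / sum(p))

  grid <- lut_grid(mus_prime = seq(0.5, 3, length.out = 6),
                   gamma = seq(1, 2, length.out = 6),
                   mua = seq(0, 1, length.out = 6))
  rho <- c(0.4, 0.5, 0.6)
  surrogate <- function(msp, gm, ma, rho) {
    0.01 * msp^1.2 * (1 + 0.25 * (gm - 1.5)) *
      exp(-sqrt(3 * ma * (ma + msp)) * rho) / (rho + 0.2)^2
  }
  vals <- array(NA_real_, c(6, 6, 6, 3))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    vals[i, j, k, ] <- surrogate(grid$mus_prime[i], grid$gamma[j],
                                 grid$mua[k], rho)
  }
  lut <- structure(list(values = vals, grid = grid,
                        valid = matrix(TRUE, 6, 6),
                        g1_used = matrix(0.9, 6, 6), se_mua0 = NULL,
                        rho_mm = rho, tilt_deg = 0, family = "synthetic",
                        n_photons = NA_real_, seed = seed, layout = NULL),
                   class = "reflectance_lut")
  truth_idx <- c(4, 3, 2)
  truth <- c(mus_prime = grid$mus_prime[truth_idx[1]],
             gamma = grid$gamma[truth_idx[2]],
             mua = grid$mua[truth_idx[3]])
  r <- vals[truth_idx[1], truth_idx[2], truth_idx[3], ]
  list(ps = ps,
       reflectance = data.frame(rho_mm = rho, r = r),
       lut = lut, truth = truth, seed = seed)
}
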