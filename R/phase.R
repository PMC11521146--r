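#' Single-scattering phase functions
#'
#' Constructors for the three phase-function families used throughout the
#' package: Henyey-Greenstein (HG), modified Henyey-Greenstein (MHG, an HG
#' core mixed with a `cos^2` lobe) and modified power-of-cosines (MPC, a
#' `(1+cos)^N` core mixed with the same `cos^2` lobe).  All densities are
#' stored per unit cosine on `[-1, 1]` (the azimuthal `2*pi` of the
#' per-solid-angle forms divided out), so they integrate to one over
#' `mu = cos(theta)`.
#'
#' The MHG and MPC families share the property that their first two Legendre
#' moments `(g1, g2)` can be set independently (within a representable
#' region) while their moments of order three and higher differ, which is
#' what makes the pair useful for isolating the influence of higher-order
#' moments on reflectance.
#'
#' @param g Anisotropy of the pure HG function, in `[0, 1)`.
#' @param alpha Mixture weight of the HG or power-of-cosines core, in
#'   `[0, 1]`; the remaining `1 - alpha` goes to the `cos^2` lobe.
#' @param g_hg Anisotropy of the HG core of an MHG function, in `[0, 1)`.
#' @param n_pc Power-of-cosines exponent `N >= 0` (real-valued; non-integer
#'   exponents are permitted and generally required by moment matching).
#' @return An object of class `tilt_phase`.
#' @examples
#' ph <- phase_mhg(alpha = 0.9, g_hg = 0.9)
#' phase_moments(ph, 3)
#' @export
phase_hg <- function(g) {
  if (!is.numeric(g) || length(g) != 1 || g < 0 || g >= 1) {
    abort_invalid("HG anisotropy `g` must be a single value in [0, 1)")
  }
  new_phase("hg", g = g)
}

#' @rdname phase_hg
#' @export
phase_mhg <- function(alpha, g_hg) {
  if (alpha < 0 || alpha > 1) abort_invalid("MHG `alpha` must lie in [0, 1]")
  if (g_hg < 0 || g_hg >= 1) abort_invalid("MHG `g_hg` must lie in [0, 1)")
  new_phase("mhg", alpha = alpha, g_hg = g_hg)
}

#' @rdname phase_hg
#' @export
phase_mpc <- function(alpha, n_pc) {
  if (alpha < 0 || alpha > 1) abort_invalid("MPC `alpha` must lie in [0, 1]")
  if (n_pc < 0) abort_invalid("MPC exponent `n_pc` must be >= 0")
  new_phase("mpc", alpha = alpha, n_pc = n_pc)
}

new_phase <- function(family, ...) {
  structure(list(family = family, ...), class = "tilt_phase")
}

#' @export
print.tilt_phase <- function(x, ...) {
  g12 <- phase_moments(x, 2)
  pars <- switch(x$family,
    hg  = sprintf("g = %.6g", x$g),
    mhg = sprintf("alpha = %.6g, g_hg = %.6g", x$alpha, x$g_hg),
    mpc = sprintf("alpha = %.6g, N = %.6g", x$alpha, x$n_pc))
  cat(sprintf("<tilt_phase %s: %s; g1 = %.4f, g2 = %.4f, gamma = %.4f>\n",
              toupper(x$family), pars, g12[1], g12[2],
              (1 - g12[2]) / (1 - g12[1])))
  invisible(x)
}

# family code and parameters for the C++ samplers
phase_code <- function(phase) {
  switch(phase$family,
    hg  = list(fam = 0L, p1 = phase$g, p2 = 0),
    mhg = list(fam = 1L, p1 = phase$alpha, p2 = phase$g_hg),
    mpc = list(fam = 2L, p1 = phase$alpha, p2 = phase$n_pc))
}

#' First two Legendre moments with the subdiffusive parameter
#'
#' Bundles `(g1, g2)` with the derived parameter
#' `gamma = (1 - g2) / (1 - g1)` and validates the Legendre-moment bounds
#' for a nonnegative density.
#'
#' @param g1,g2 First and second Legendre moments.
#' @return A named list with `g1`, `g2` and `gamma`.
#' @export
moment_set <- function(g1, g2) {
  if (g1 <= -1 || g1 >= 1) abort_invalid("`g1` must lie in (-1, 1)")
  if (g2 < -0.5 || g2 >= 1) abort_invalid("`g2` must lie in [-0.5, 1)")
  structure(list(g1 = g1, g2 = g2, gamma = (1 - g2) / (1 - g1)),
            class = "moment_set")
}

#' Evaluate a phase-function density
#'
#' Density per unit cosine at `mu = cos(theta)`.
#'
#' @param phase A [phase_hg()], [phase_mhg()] or [phase_mpc()] object.
#' @param mu Cosines in `[-1, 1]`.
#' @return Density values (nonnegative, integrating to one over `[-1, 1]`).
#' @export
phase_pdf <- function(phase, mu) {
  stopifnot(inherits(phase, "tilt_phase"))
  if (any(mu < -1 | mu > 1)) abort_invalid("`mu` must lie in [-1, 1]")
  switch(phase$family,
    hg  = pdf_hg(phase$g, mu),
    mhg = phase$alpha * pdf_hg(phase$g_hg, mu) +
          (1 - phase$alpha) * 1.5 * mu^2,
    mpc = phase$alpha * pdf_pc(phase$n_pc, mu) +
          (1 - phase$alpha) * 1.5 * mu^2)
}

pdf_hg <- function(g, mu) {
  if (g < 1e-14) return(rep(0.5, length(mu)))
  0.5 * (1 - g^2) * (1 + g^2 - 2 * g * mu)^(-1.5)
}

pdf_pc <- function(N, mu) {
  # (N+1)/2^(N+1) (1+mu)^N, written to stay finite for large N
  exp(log(N + 1) - (N + 1) * log(2) + N * log1p(mu))
}

#' Analytic Legendre moments of a phase function
#'
#' Closed-form moments per family: `g^n` for HG; for MHG and MPC the `cos^2`
#' lobe contributes only at order two (`2/5`), the core contributing
#' `alpha * g_core^n` (HG core) or `alpha * gPC_n` with the recursion
#' `gPC_1 = N/(N+2)`, `gPC_n = gPC_{n-1} (N-n+1)/(N+n+1)`.
#'
#' @inheritParams phase_pdf
#' @param n_max Highest order to return (`>= 1`).
#' @return Numeric vector `g_1 .. g_{n_max}`.
#' @export
phase_moments <- function(phase, n_max) {
  stopifnot(inherits(phase, "tilt_phase"), n_max >= 1)
  n_max <- as.integer(n_max)
  out <- switch(phase$family,
    hg = phase$g^seq_len(n_max),
    mhg = {
      gn <- phase$alpha * phase$g_hg^seq_len(n_max)
      if (n_max >= 2) gn[2] <- gn[2] + 0.4 * (1 - phase$alpha)
      gn
    },
    mpc = {
      gn <- phase$alpha * pc_moments(phase$n_pc, n_max)
      if (n_max >= 2) gn[2] <- gn[2] + 0.4 * (1 - phase$alpha)
      gn
    })
  out
}

pc_moments <- function(N, n_max) {
  gpc <- numeric(n_max)
  gpc[1] <- N / (N + 2)
  if (n_max >= 2) {
    for (n in 2:n_max) gpc[n] <- gpc[n - 1] * (N - n + 1) / (N + n + 1)
  }
  gpc
}

#' Legendre moments by quadrature
#'
#' Computes `g_n = integral of P_n(mu) p(mu) dmu` by Gauss-Legendre
#' quadrature for an arbitrary density over the cosine.  The density must be
#' normalized to one (checked to `1e-6`).
#'
#' @param pdf A function of `mu` returning the density per unit cosine.
#' @param n_max Highest order to return.
#' @param n_nodes Number of quadrature nodes.
#' @return Numeric vector `g_1 .. g_{n_max}`.
#' @export
numeric_moments <- function(pdf, n_max, n_nodes = 1024L) {
  stopifnot(is.function(pdf), n_max >= 1)
  q <- default_quad(n_nodes)
  p <- pdf(q$x)
  if (any(p < -1e-12)) abort_invalid("density is negative on [-1, 1]")
  norm <- sum(q$w * p)
  if (abs(norm - 1) > 1e-6) {
    abort_invalid(sprintf("density integrates to %.8f, not 1", norm))
  }
  P <- legendre_matrix(n_max, q$x)
  as.numeric(P[-1, , drop = FALSE] %*% (q$w * p))
}

#' Sample scattering cosines
#'
#' Draws deflection cosines from a phase function by exact inverse-CDF
#' sampling of each mixture component (HG by its standard inversion, the
#' `cos^2` lobe by a cube root, the power-of-cosines core by a power).
#' Uses R's RNG stream, so results are reproducible under [set.seed()].
#'
#' @inheritParams phase_pdf
#' @param n Number of samples.
#' @return Numeric vector of cosines in `[-1, 1]`.
#' @export
sample_cos_theta <- function(phase, n) {
  stopifnot(inherits(phase, "tilt_phase"))
  pc <- phase_code(phase)
  cpp_sample_mu(as.integer(n), pc$fam, pc$p1, pc$p2)
}

#' Solve family parameters from target moments
#'
#' Finds the MHG or MPC parameters whose analytic first two Legendre moments
#' equal the target `(g1, g2)`.  For MHG, eliminating `alpha` leaves an
#' exact quadratic in the core anisotropy whose positive root is taken; for
#' MPC the exponent is found by bisection of the monotone moment map on
#' `N` in `[2 g1/(1 - g1), 1e4]` (the lower end is the pure power-of-cosines
#' boundary where `alpha = 1`).  Targets outside the representable region
#' raise an infeasibility error naming the violated constraint rather than
#' clamping.
#'
#' @param family `"mhg"` or `"mpc"`.
#' @param g1,g2 Target moments, or a [moment_set()] passed as `g1`.
#' @return A [phase_mhg()] or [phase_mpc()] object reproducing `(g1, g2)`.
#' @examples
#' ph <- phase_from_moments("mhg", 0.9, 0.85)
#' phase_moments(ph, 2)
#' @export
phase_from_moments <- function(family, g1, g2 = NULL) {
  if (inherits(g1, "moment_set")) {
    g2 <- g1$g2
    g1 <- g1$g1
  }
  ms <- moment_set(g1, g2)  # validates bounds
  family <- match.arg(family, c("mhg", "mpc"))
  if (g1 < 0) abort_infeasible("targets with g1 < 0 are not representable")
  if (family == "mhg") solve_mhg(g1, g2) else solve_mpc(g1, g2)
}

solve_mhg <- function(g1, g2) {
  if (g1 < 1e-12) {
    # mixture of isotropic HG and the cos^2 lobe: g2 = 0.4 (1 - alpha)
    if (g2 < 0 || g2 > 0.4) {
      abort_infeasible("at g1 = 0 the MHG family covers only g2 in [0, 0.4]")
    }
    return(phase_mhg(alpha = 1 - g2 / 0.4, g_hg = 0))
  }
  if (g2 < g1^2 - 1e-12) {
    abort_infeasible(sprintf(
      "MHG requires g2 >= g1^2 (alpha <= 1); target (%.4g, %.4g)", g1, g2))
  }
  if (g2 > g1 + 0.4 * (1 - g1) + 1e-12) {
    abort_infeasible(sprintf(
      "MHG requires g2 <= g1 + 0.4 (1 - g1) (alpha >= 0); target (%.4g, %.4g)",
      g1, g2))
  }
  # g1 = alpha g, g2 = alpha g^2 + 2/5 (1 - alpha)  =>
  # g1 g^2 + (2/5 - g2) g - 2/5 g1 = 0
  b <- 0.4 - g2
  g <- (-b + sqrt(b^2 + 1.6 * g1^2)) / (2 * g1)
  g <- min(max(g, g1), 1 - 1e-15)
  phase_mhg(alpha = g1 / g, g_hg = g)
}

solve_mpc <- function(g1, g2) {
  if (g1 < 1e-12) {
    if (g2 < 0 || g2 > 0.4) {
      abort_infeasible("at g1 = 0 the MPC family covers only g2 in [0, 0.4]")
    }
    return(phase_mpc(alpha = 1 - g2 / 0.4, n_pc = 0))
  }
  # g2 as a function of N at fixed g1 (alpha = g1 / gPC1) is monotone
  g2_of_n <- function(N) {
    gpc1 <- N / (N + 2)
    gpc2 <- gpc1 * (N - 1) / (N + 3)
    a <- g1 / gpc1
    a * gpc2 + 0.4 * (1 - a)
  }
  n_lo <- 2 * g1 / (1 - g1)  # alpha = 1: pure power-of-cosines
  n_hi <- 1e4
  if (g2 < g2_of_n(n_lo) - 1e-12) {
    abort_infeasible(sprintf(
      "MPC requires g2 >= the pure power-of-cosines value %.4g at g1 = %.4g (alpha <= 1)",
      g2_of_n(n_lo), g1))
  }
  if (g2 > g2_of_n(n_hi) + 1e-12) {
    abort_infeasible(sprintf(
      "MPC requires g2 <= %.4g at g1 = %.4g (alpha >= 0 at N -> Inf)",
      g2_of_n(n_hi), g1))
  }
  N <- bisect(function(N) g2_of_n(N) - g2, n_lo, n_hi)
  phase_mpc(alpha = g1 * (N + 2) / N, n_pc = N)
}

# plain bisection to ~1e-12 relative; both solvers feed exact monotone maps
bisect <- function(f, lo, hi, tol = 1e-12, maxit = 200L) {
  flo <- f(lo)
  if (abs(flo) < tol) return(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) < tol * max(1, abs(mid))) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  mid
}
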