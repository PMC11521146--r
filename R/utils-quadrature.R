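# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch via the symmetric
# tridiagonal Jacobi matrix) and the Legendre polynomial recurrence.  Kept
# dependency-free; both are exercised indirectly by every moment check.

gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
}

# rows P0..Pnmax evaluated at x
legendre_matrix <- function(n_max, x) {
  P <- matrix(0, n_max + 1, length(x))
  P[1, ] <- 1
  if (n_max >= 1) P[2, ] <- x
  if (n_max >= 2) {
    for (n in 2:n_max) {
      P[n + 1, ] <- ((2 * n - 1) * x * P[n, ] - (n - 1) * P[n - 1, ]) / n
    }
  }
  P
}

# memoised default quadrature
the_quad <- new.env(parent = emptyenv())
default_quad <- function(n = 1024L) {
  key <- as.character(n)
  if (is.null(the_quad[[key]])) the_quad[[key]] <- gauss_legendre(n)
  the_quad[[key]]
}

# weighted quantile with linear interpolation inside the containing bin;
# `breaks` has length(weights) + 1
weighted_quantile_hist <- function(breaks, weights, prob) {
  tot <- sum(weights)
  if (tot <= 0) abort_invalid("empty histogram: quantile undefined")
  cw <- cumsum(weights) / tot
  i <- which(cw >= prob)[1]
  lo <- breaks[i]
  hi <- breaks[i + 1]
  prev <- if (i == 1) 0 else cw[i - 1]
  lo + (hi - lo) * (prob - prev) / (cw[i] - prev)
}
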