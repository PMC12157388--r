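# Matern-5/2 covariance and numerically-hygienic Cholesky factorization.
# Both GP modules (density, expression) share these primitives.

#' Matern-5/2 covariance between two point sets
#'
#' \eqn{k(r) = s^2 (1 + a r + a^2 r^2 / 3) e^{-a r}} with
#' \eqn{a = \sqrt{5}/\ell}. Smooth but not infinitely smooth, the standard
#' choice for biological response surfaces.
#'
#' @param a,b numeric matrices (rows are points) with equal column count.
#' @param length_scale kernel length-scale \eqn{\ell > 0}.
#' @param amplitude marginal standard deviation \eqn{s}.
#' @return `nrow(a) x nrow(b)` covariance matrix.
#' @keywords internal
matern52 <- function(a, b, length_scale, amplitude = 1) {
  stopifnot(length_scale > 0, amplitude > 0)
  r <- sqrt(cross_dist2(a, b))
  z <- sqrt(5) * r / length_scale
  amplitude^2 * (1 + z + z^2 / 3) * exp(-z)
}

# Cholesky with escalating diagonal jitter (none -> jitter -> max_jitter);
# errors if the matrix stays indefinite. Returns the lower factor. Trying
# the unjittered matrix first keeps well-posed cases bit-exact.
chol_jitter <- function(K, jitter = 1e-10, max_jitter = 1e-4) {
  n <- nrow(K)
  j <- 0
  scale <- mean(diag(K))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  repeat {
    L <- tryCatch(t(chol(K + diag(j * scale, n))), error = function(e) NULL)
    if (!is.null(L)) {
      attr(L, "jitter") <- j
      return(L)
    }
    if (j >= max_jitter)
      stop(sprintf(
        "Cholesky factorization failed even with jitter %g (n = %d)", j, n))
    j <- if (j == 0) jitter else j * 100
  }
}

# Median-distance heuristic for a GP length-scale, computed on a subsample
# (or landmark set) for large n. `mult` widens the scale: density surfaces
# need pooling across many noisy per-cell observations.
median_heuristic <- function(coords, mult = 1, max_points = 1000L,
                             seed = 1L) {
  n <- nrow(coords)
  if (n > max_points) {
    idx <- with_seed(seed, sample.int(n, max_points))
    coords <- coords[idx, , drop = FALSE]
  }
  d2 <- cross_dist2(coords, coords)
  m <- sqrt(median(d2[upper.tri(d2)]))
  if (!is.finite(m) || m <= 0)
    stop("median-distance heuristic degenerate: all points coincide")
  mult * m
}
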