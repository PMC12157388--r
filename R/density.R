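# Condition-specific log-density estimation over the cell-state space.
#
# Model: the distance r_i from cell i to its nearest neighbor is treated as
# the waiting distance of a locally homogeneous Poisson point process with
# log-rate g(x_i) in intrinsic dimension d:
#
#   log p(r_i | g_i) = g_i + log d + log V_d + (d-1) log r_i
#                      - exp(g_i) V_d r_i^d,
#
# where V_d is the volume of the unit d-ball. A Gaussian-process prior
# (Matern-5/2) over g yields a MAP estimate of the continuous log-density
# (natural-log cells per volume) and a Laplace approximation gives pointwise
# predictive uncertainty — the ingredients of the differential-abundance
# statistics.

unit_ball_volume <- function(d) {
  stopifnot(d > 0)
  exp((d / 2) * log(pi) - lgamma(d / 2 + 1))
}

#' Estimate the intrinsic dimensionality of the cell-state manifold
#'
#' Maximum-likelihood two-nearest-neighbor estimator:
#' \eqn{\hat d = 1 / \mathrm{mean}_i \log(r_{2i}/r_{1i})} where
#' \eqn{r_{1i}, r_{2i}} are the first and second nearest-neighbor distances
#' of cell *i*. A single global dimension is assumed across the dataset; the
#' estimate is scale-invariant and is clipped to `[1, ambient dimension]`.
#'
#' @param coords cell-state coordinate matrix (>= 50 cells).
#' @return positive scalar dimension estimate.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(400), 200, 2)
#' estimate_intrinsic_dimension(x)  # close to 2
#' @export
estimate_intrinsic_dimension <- function(coords) {
  coords <- check_matrix(coords)
  if (nrow(coords) < 50)
    stop("at least 50 cells are required for a stable dimension estimate")
  nn <- knn_exact(coords, 2L)
  r1 <- nn$dist[, 1]
  r2 <- nn$dist[, 2]
  dup <- r1 == 0
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate points from dimension estimate",
                    sum(dup)))
    r1 <- r1[!dup]; r2 <- r2[!dup]
    if (length(r1) < 50)
      stop("fewer than 50 distinct points after dropping duplicates")
  }
  ratios <- log(r2 / r1)
  m <- mean(ratios)
  if (m == 0)
    stop("degenerate input: all first and second neighbor distances equal")
  min(max(1 / m, 1), ncol(coords))
}

# Per-cell log-likelihood of nearest-neighbor distance r given log-rate g.
nn_loglik <- function(g, r, d, vd = unit_ball_volume(d)) {
  g + log(d) + log(vd) + (d - 1) * log(r) - exp(g) * vd * r^d
}

#' Fit a Gaussian-process log-density model for one condition
#'
#' MAP estimation of a latent log-density function with a Matern-5/2 GP
#' prior and the nearest-neighbor-distance likelihood above; predictive mean
#' and standard deviation come from a Laplace approximation at the MAP and
#' are available at arbitrary cell states via [predict_log_density()].
#'
#' For `n > landmark_threshold` cells the latent function is represented on
#' k-means inducing points (see [select_landmarks()]) so cost stays linear
#' in cells; below the threshold the representation is exact.
#'
#' @param coords cell-state matrix for the cells of one condition (>= 50).
#' @param intrinsic_dim global manifold dimension, from
#'   [estimate_intrinsic_dimension()] or a user override.
#' @param condition label stored with the fit.
#' @param length_scale GP length-scale; `NULL` for the heuristic
#'   `ls_mult` x the median 25-NN distance (the prior must pool across many
#'   cells because a single nearest-neighbor distance is a very noisy
#'   density observation; the default multiplier pools on the order of a
#'   hundred cells in typical embeddings).
#' @param amplitude GP prior standard deviation of the log-density around
#'   its learned constant mean; `NULL` for `sd` of the pointwise MLE.
#' @param ls_mult multiplier on the length-scale heuristic (default 6).
#' @param landmark_threshold switch to inducing points above this n.
#' @param n_landmarks inducing-point count in sparse mode.
#' @param maxit optimizer iteration cap; non-convergence is an error
#'   carrying the final gradient norm.
#' @param seed seed for inducing-point selection.
#' @param uncertainty Gaussian-approximation flavor for the predictive
#'   variance: `"moment_matched"` (default; per-cell likelihood curvature
#'   replaced by the exact single-site posterior precision
#'   `1/trigamma(1)`, slightly conservative) or `"laplace"` (raw mode
#'   curvature).
#' @return object of class `kompot_density` with fields `condition`,
#'   `n_cells`, `intrinsic_dim`, `predictive_mean` and `predictive_sd` at
#'   the training states, and an opaque `model_state` for prediction.
#' @export
fit_density <- function(coords, intrinsic_dim = NULL, condition = "cond",
                        length_scale = NULL, amplitude = NULL, ls_mult = 6,
                        landmark_threshold = 5000L, n_landmarks = 2000L,
                        maxit = 1000L, seed = 1L,
                        uncertainty = c("moment_matched", "laplace")) {
  uncertainty <- match.arg(uncertainty)
  coords <- check_matrix(coords)
  n <- nrow(coords)
  if (n < 50) stop("at least 50 cells are required to fit a density")
  if (is.null(intrinsic_dim)) intrinsic_dim <- estimate_intrinsic_dimension(coords)
  d <- intrinsic_dim
  if (d <= 0) stop("intrinsic_dim must be positive")

  k_bw <- min(25L, n - 1L)
  nn <- knn_exact(coords, k_bw)
  r <- nn$dist[, 1]
  if (any(r == 0)) {
    # duplicate points break the nearest-neighbor likelihood (r = 0); the
    # perturbation must clear the floating-point cancellation floor of the
    # distance computation, so it is scaled to the data
    dupi <- which(r == 0)
    jit <- max(1e-10, 1e-7 * median(nn$dist[, k_bw]))
    warning(sprintf("%d duplicate points perturbed by %.3g jitter",
                    length(dupi), jit))
    coords[dupi, ] <- coords[dupi, , drop = FALSE] +
      with_seed(seed, matrix(rnorm(length(dupi) * ncol(coords), sd = jit),
                             length(dupi)))
    nn <- knn_exact(coords, k_bw)
    r <- nn$dist[, 1]
    if (any(r == 0)) stop("duplicate points persist after jitter")
  }
  vd <- unit_ball_volume(d)
  # pointwise MLE of g (exp(g) Vd r^d = 1) seeds the optimizer and the
  # amplitude heuristic
  g0 <- -log(vd) - d * log(r)
  if (is.null(length_scale)) length_scale <- ls_mult * median(nn$dist[, k_bw])
  if (is.null(amplitude)) {
    # robust spread: single-cell MLEs have wild tails (jittered duplicates)
    qs <- quantile(g0, c(0.01, 0.99), names = FALSE)
    amplitude <- max(sd(pmin(pmax(g0, qs[1]), qs[2])), 1)
  }

  sparse <- n > landmark_threshold
  if (sparse) {
    lm <- select_landmarks(coords, k = min(n_landmarks, n), t = 10L,
                           seed = seed)
    Z <- lm$points
    Kuu <- matern52(Z, Z, length_scale, amplitude)
    Luu <- chol_jitter(Kuu, 1e-8)
    Kxu <- matern52(coords, Z, length_scale, amplitude)
    A <- t(forwardsolve(Luu, t(Kxu)))      # K_xu Luu^-T, n x m
  } else {
    Z <- coords
    K <- matern52(coords, coords, length_scale, amplitude)
    Luu <- chol_jitter(K, 1e-8)
    A <- Luu                               # exact: g = m + L z
  }
  m_lat <- ncol(A)

  # whitened parameterization theta = (mean, z), g = mean + A z, z ~ N(0, I)
  obj <- function(theta) {
    g <- theta[1] + as.vector(A %*% theta[-1])
    0.5 * sum(theta[-1]^2) - sum(nn_loglik(g, r, d, vd))
  }
  grr <- function(theta) {
    z <- theta[-1]
    g <- theta[1] + as.vector(A %*% z)
    u <- 1 - exp(g) * vd * r^d            # d loglik / d g
    c(-sum(u), z - as.vector(crossprod(A, u)))
  }
  theta0 <- c(mean(g0), rep(0, m_lat))
  fit <- optim(theta0, obj, grr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  if (fit$convergence != 0) {
    gn <- sqrt(sum(grr(fit$par)^2))
    stop(sprintf(
      "density MAP optimization did not converge (code %d, |grad| = %.3g)",
      fit$convergence, gn))
  }
  mean_const <- fit$par[1]
  z_hat <- fit$par[-1]
  g_hat <- mean_const + as.vector(A %*% z_hat)

  # Gaussian approximation over the full parameter vector (mean, z).
  # Site curvature: the mode curvature of the per-cell likelihood is
  # exp(g) Vd r^d (= 1 at the per-cell optimum), but the likelihood is a
  # skewed log-Gamma form whose exact single-site posterior variance is
  # trigamma(1) = pi^2/6, not 1/curvature. "moment_matched" (default)
  # divides the curvature by trigamma(1) — slightly conservative where
  # many cells pool, honest in sparse regions; "laplace" keeps the raw
  # mode curvature. Including the learned constant mean in the precision
  # matters: its error shifts the whole log-density coherently.
  #   B = [ sum(h)  (A^T h)^T ]
  #       [ A^T h   I + A^T H A ]
  h <- exp(g_hat) * vd * r^d
  if (uncertainty == "moment_matched") h <- h / trigamma(1)
  ah <- as.vector(crossprod(A, h))
  B <- rbind(c(sum(h), ah),
             cbind(ah, diag(m_lat) + crossprod(A * sqrt(h))))
  LB <- chol_jitter(B, 1e-12)

  state <- list(Z = Z, Luu = Luu, LB = LB, z_hat = z_hat,
                mean_const = mean_const, length_scale = length_scale,
                amplitude = amplitude, sparse = sparse,
                train_coords = if (sparse) NULL else coords)
  est <- structure(list(condition = condition, n_cells = n,
                        intrinsic_dim = d, model_state = state,
                        train_states = coords),
                   class = "kompot_density")
  pr <- predict_log_density(est, coords)
  est$predictive_mean <- pr$mean
  est$predictive_sd <- pr$sd
  est
}

#' Predict log-density (with uncertainty) at arbitrary cell states
#'
#' Evaluates the fitted continuous density anywhere in the cell-state space,
#' including states predominantly observed in another condition — the basis
#' of cross-condition abundance comparison.
#'
#' @param object a fitted `kompot_density`.
#' @param query matrix of states (columns must match training dimension).
#' @return list with numeric vectors `mean` (log cells per volume) and `sd`
#'   (`>= 0`), one entry per query row.
#' @export
predict_log_density <- function(object, query) {
  stopifnot(inherits(object, "kompot_density"))
  st <- object$model_state
  query <- check_matrix(query)
  if (nrow(query) == 0)
    return(list(mean = numeric(0), sd = numeric(0)))
  if (ncol(query) != ncol(st$Z))
    stop(sprintf("query has %d dims but the model was trained on %d",
                 ncol(query), ncol(st$Z)))
  amp2 <- st$amplitude^2
  if (st$sparse) {
    Kqu <- matern52(query, st$Z, st$length_scale, st$amplitude)
    Aq <- t(forwardsolve(st$Luu, t(Kqu)))        # q x m
    mu <- st$mean_const + as.vector(Aq %*% st$z_hat)
    Tm <- forwardsolve(st$LB, rbind(1, t(Aq)))   # (m+1) x q, incl. mean
    v_lat <- colSums(Tm^2)
    v_prior <- pmax(amp2 - rowSums(Aq^2), 0)     # Nystrom gap
  } else {
    Kqx <- matern52(query, st$Z, st$length_scale, st$amplitude)
    V <- forwardsolve(st$Luu, t(Kqx))            # n x q, = L^-1 k_*
    mu <- st$mean_const +
      as.vector(Kqx %*% backsolve(t(st$Luu), st$z_hat))
    Tm <- forwardsolve(st$LB, rbind(1, V))       # (n+1) x q, incl. mean
    v_lat <- colSums(Tm^2)
    v_prior <- pmax(amp2 - colSums(V^2), 0)
  }
  list(mean = mu, sd = sqrt(v_prior + v_lat))
}

#' @export
print.kompot_density <- function(x, ...) {
  cat(sprintf(
    "<kompot_density> condition '%s': %d cells, intrinsic dim %.2f\n",
    x$condition, x$n_cells, x$intrinsic_dim))
  cat(sprintf("  log-density at training states: [%.2f, %.2f], median sd %.3f\n",
              min(x$predictive_mean), max(x$predictive_mean),
              median(x$predictive_sd)))
  invisible(x)
}
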