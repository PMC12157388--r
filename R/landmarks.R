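# Landmark selection by k-means with k-means++ initialization and a fixed
# number of Lloyd iterations. A fixed iteration count keeps the whole
# landmark scheme O(t * k * d * n) — linear in cells — which is what makes
# the landmark GP and its k x k covariance tractable on large datasets.

#' Select landmark cell states by capped k-means
#'
#' k-means++ seeding followed by exactly `t` Lloyd iterations, fully
#' deterministic given `seed`. Empty clusters are re-seeded at the point
#' currently farthest from its assigned centroid (logged).
#'
#' @param coords cell-state matrix (n x d).
#' @param k number of landmarks (`1 <= k <= n`).
#' @param t number of Lloyd iterations (`>= 1`, default 10).
#' @param seed RNG seed for the k-means++ draw.
#' @return object of class `kompot_landmarks`: `points` (k x d), `k`, `t`,
#'   `seed`, `objective` (within-cluster sum of squares per iteration,
#'   non-increasing), `assignment`.
#' @examples
#' lm <- select_landmarks(matrix(rnorm(200), 100, 2), k = 10, seed = 1)
#' lm$objective
#' @export
select_landmarks <- function(coords, k, t = 10L, seed = 1L) {
  coords <- check_matrix(coords)
  n <- nrow(coords)
  if (k > n) stop(sprintf("k = %d exceeds the number of points (%d)", k, n))
  if (k < 1) stop("k must be >= 1")
  if (t < 1) stop("t must be >= 1")

  centers <- with_seed(seed, {
    # k-means++ seeding
    C <- matrix(0, k, ncol(coords))
    first <- sample.int(n, 1)
    C[1, ] <- coords[first, ]
    if (k > 1) {
      d2 <- rowSums(sweep(coords, 2, C[1, ])^2)
      for (j in 2:k) {
        if (all(d2 == 0)) {
          pick <- sample.int(n, 1)  # duplicate-heavy input: uniform fallback
        } else {
          pick <- sample.int(n, 1, prob = d2)
        }
        C[j, ] <- coords[pick, ]
        d2 <- pmin(d2, rowSums(sweep(coords, 2, C[j, ])^2))
      }
    }
    C
  })

  objective <- numeric(t)
  assign_idx <- integer(n)
  for (it in seq_len(t)) {
    d2 <- cross_dist2(coords, centers)
    assign_idx <- max.col(-d2, ties.method = "first")
    best <- d2[cbind(seq_len(n), assign_idx)]
    objective[it] <- sum(best)
    for (j in seq_len(k)) {
      members <- assign_idx == j
      if (!any(members)) {
        far <- which.max(best)
        message(sprintf(
          "landmark %d lost all members; re-seeded at farthest point %d",
          j, far))
        centers[j, ] <- coords[far, ]
        best[far] <- 0
        assign_idx[far] <- j
      } else {
        centers[j, ] <- colMeans(coords[members, , drop = FALSE])
      }
    }
  }
  structure(list(points = centers, k = as.integer(k), t = as.integer(t),
                 seed = as.integer(seed), objective = objective,
                 assignment = assign_idx),
            class = "kompot_landmarks")
}

#' @export
print.kompot_landmarks <- function(x, ...) {
  cat(sprintf("<kompot_landmarks> k = %d (t = %d Lloyd iterations, seed %d)\n",
              x$k, x$t, x$seed))
  invisible(x)
}
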