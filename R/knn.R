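# Exact k-nearest-neighbor search (brute force, chunked) and the symmetric
# kNN affinity graph feeding the diffusion map. Desk-scale datasets
# (<= tens of thousands of cells) do not need an approximate index; an exact
# scan keeps results deterministic and testable against an all-pairs oracle.

# Exact kNN by chunked all-pairs scan. Ties are broken by cell index so the
# result is unique. Returns list(idx, dist): n x k matrices, self excluded.
knn_exact <- function(coords, k, chunk = 512L) {
  coords <- check_matrix(coords)
  n <- nrow(coords)
  stopifnot(k >= 1, k < n)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  sq <- rowSums(coords^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    rows <- s:e
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(coords[rows, , drop = FALSE], coords)
    d2[d2 < 0] <- 0
    d2[cbind(seq_along(rows), rows)] <- Inf  # exclude self
    for (i in seq_along(rows)) {
      o <- order(d2[i, ], seq_len(n))[seq_len(k)]
      idx[rows[i], ] <- o
      dst[rows[i], ] <- sqrt(d2[i, o])
    }
  }
  list(idx = idx, dist = dst)
}

#' Build a symmetric k-nearest-neighbor affinity graph
#'
#' Computes exact Euclidean k-nearest neighbors in the latent space and an
#' adaptive-bandwidth Gaussian affinity: \eqn{K_{ij} =
#' \exp(-d_{ij}^2 / (\sigma_i \sigma_j))} where \eqn{\sigma_i} is the
#' distance from cell *i* to its k-th neighbor. The directed kernel is
#' symmetrized by its arithmetic mean, guaranteeing a real spectrum
#' downstream.
#'
#' @param embedding a [latent_embedding()] (or bare coordinate matrix).
#' @param n_neighbors number of neighbors, `>= 2` and `< n` cells.
#' @return object of class `kompot_knn_graph`: `idx`, `dist` (n x k),
#'   `affinity` (sparse symmetric `dgCMatrix`), `bandwidth` (per-cell
#'   \eqn{\sigma_i}), `n_neighbors`.
#' @export
build_knn_graph <- function(embedding, n_neighbors = 30L) {
  coords <- if (inherits(embedding, "kompot_embedding")) embedding$coords
            else check_matrix(embedding)
  n <- nrow(coords)
  if (n_neighbors < 2 || n_neighbors >= n)
    stop(sprintf("n_neighbors must be in [2, %d), got %d", n, n_neighbors))
  nn <- knn_exact(coords, n_neighbors)
  zero <- which(nn$dist[, 1] == 0)
  if (length(zero)) {
    ids <- if (!is.null(rownames(coords))) rownames(coords)[zero]
           else as.character(zero)
    stop("duplicate points (zero nearest-neighbor distance) for cells: ",
         paste(head(ids, 10), collapse = ", "))
  }
  sigma <- nn$dist[, n_neighbors]
  i <- rep(seq_len(n), each = n_neighbors)
  j <- as.vector(t(nn$idx))
  d <- as.vector(t(nn$dist))
  w <- exp(-d^2 / (sigma[i] * sigma[j]))
  A <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  A <- (A + Matrix::t(A)) / 2
  structure(list(idx = nn$idx, dist = nn$dist, affinity = A,
                 bandwidth = sigma, n_neighbors = as.integer(n_neighbors)),
            class = "kompot_knn_graph")
}

# Connected components of a symmetric sparse adjacency pattern via BFS.
graph_components <- function(A) {
  n <- nrow(A)
  Ap <- as(A, "CsparseMatrix")
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- Ap@i[seq.int(Ap@p[v] + 1L, length.out = Ap@p[v + 1L] - Ap@p[v])] + 1L
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}
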