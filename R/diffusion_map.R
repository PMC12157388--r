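#' Compute a diffusion-map cell-state space
#'
#' Spectral embedding of the adaptive-bandwidth kNN kernel: the affinity is
#' density-normalized with anisotropy exponent `alpha` (the
#' Laplace--Beltrami limit at `alpha = 1`, decoupling manifold geometry from
#' sampling density — essential here because density is modeled separately),
#' converted to a Markov transition operator, and eigendecomposed. The top
#' non-trivial eigenvectors are the cell-state coordinates shared by every
#' condition.
#'
#' Each eigenvector's sign is fixed so that its largest-magnitude entry is
#' positive, making results reproducible up to numerical tolerance.
#'
#' @param embedding a [latent_embedding()] or coordinate matrix.
#' @param n_components number of diffusion components to retain (`>= 2`).
#' @param n_neighbors kNN graph size (adaptive bandwidth = distance to the
#'   `n_neighbors`-th neighbor).
#' @param alpha anisotropic normalization exponent in `[0, 1]`; default 1.
#' @param scale_by_eigenvalues multiply each component by its eigenvalue
#'   (off by default; downstream GP kernels have their own length-scales).
#' @return object of class `kompot_diffmap`: `coords` (cells x
#'   `n_components`, rownames = cell ids), `eigenvalues` (non-increasing,
#'   all `<= 1`, trivial unit eigenvalue dropped), `n_neighbors`,
#'   `kernel_params`.
#' @examples
#' emb <- latent_embedding(matrix(rnorm(600), 200, 3),
#'                         condition = rep(c("a", "b"), 100))
#' dm <- compute_diffusion_map(emb, n_components = 3, n_neighbors = 10)
#' dm$eigenvalues
#' @export
compute_diffusion_map <- function(embedding, n_components = 10L,
                                  n_neighbors = 30L, alpha = 1,
                                  scale_by_eigenvalues = FALSE) {
  coords <- if (inherits(embedding, "kompot_embedding")) embedding$coords
            else check_matrix(embedding)
  n <- nrow(coords)
  if (n_components < 2) stop("n_components must be >= 2")
  if (n_components >= n) stop("n_components must be < number of cells")
  graph <- build_knn_graph(coords, n_neighbors)
  W <- graph$affinity

  comp <- graph_components(W)
  if (max(comp) > 1L)
    stop(sprintf(paste0("kNN graph is disconnected (%d components); a ",
                        "single connected manifold is assumed. Increase ",
                        "n_neighbors."), max(comp)))

  # anisotropic normalization W' = D^-alpha W D^-alpha
  q <- Matrix::rowSums(W)
  if (alpha != 0) {
    inv_q <- q^(-alpha)
    W <- Matrix::Diagonal(x = inv_q) %*% W %*% Matrix::Diagonal(x = inv_q)
  }
  # symmetric conjugate S = D^-1/2 W' D^-1/2 of the Markov operator
  d1 <- Matrix::rowSums(W)
  inv_sq <- 1 / sqrt(d1)
  S <- Matrix::Diagonal(x = inv_sq) %*% W %*% Matrix::Diagonal(x = inv_sq)
  S <- as.matrix(Matrix::forceSymmetric(S))

  eig <- eigen(S, symmetric = TRUE)
  nev <- n_components + 1L
  vals <- eig$values[seq_len(nev)]
  vecs <- eig$vectors[, seq_len(nev), drop = FALSE]
  vals <- pmin(vals, 1)  # clamp round-off above the Markov bound

  # back-transform to right eigenvectors of the Markov operator; the global
  # factor sqrt(sum(d1)) makes the trivial eigenvector the constant 1
  psi <- vecs * inv_sq * sqrt(sum(d1))
  # drop the trivial (unit) pair
  vals <- vals[-1]
  psi <- psi[, -1, drop = FALSE]

  # sign convention: largest-magnitude entry positive
  for (jj in seq_len(ncol(psi))) {
    m <- which.max(abs(psi[, jj]))
    if (psi[m, jj] < 0) psi[, jj] <- -psi[, jj]
  }
  if (scale_by_eigenvalues) psi <- sweep(psi, 2, vals, "*")

  rownames(psi) <- rownames(coords)
  colnames(psi) <- sprintf("DC%d", seq_len(ncol(psi)))
  structure(list(coords = psi, eigenvalues = vals,
                 n_neighbors = as.integer(n_neighbors),
                 kernel_params = list(bandwidth_rule = "knn_adaptive",
                                      alpha = alpha,
                                      scale_by_eigenvalues = scale_by_eigenvalues)),
            class = "kompot_diffmap")
}

#' @export
print.kompot_diffmap <- function(x, ...) {
  cat(sprintf("<kompot_diffmap> %d cells x %d components\n",
              nrow(x$coords), ncol(x$coords)))
  cat("eigenvalues:", paste(sprintf("%.4f", head(x$eigenvalues, 6)),
                            collapse = ", "),
      if (length(x$eigenvalues) > 6) "...\n" else "\n")
  invisible(x)
}
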