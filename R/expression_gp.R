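# Condition-specific GP regression from cell state to log-normalized
# expression, in the landmark (inducing-point) formulation.
#
# All genes of one condition share a Matern-5/2 kernel and a homoskedastic
# noise variance, so the expensive factorizations are done once and the
# k x k posterior covariance at the landmarks is gene-independent: the
# per-gene Mahalanobis statistics downstream differ only through the mean
# vectors. (Per-gene kernels would make "thousands of genes within minutes"
# impossible.)
#
# With landmarks Z (m of them), K_uu = K(Z,Z), K_ux = K(Z,X), noise s^2:
#   A   = L_uu^-1 K_ux / s          (m x n, L_uu lower Cholesky of K_uu)
#   B   = I + A A^T,  L_B = chol(B)
#   q(u) = N(mu_u, S_u),  mu_u = s^-1 L_uu B^-1 A y,
#                         S_u  = L_uu B^-1 L_uu^T
# which at Z = X and s -> 0 recovers exact GP interpolation, and at Z = X
# with any s equals the exact GP posterior.

#' Fit condition-specific gene-expression GPs on a landmark set
#'
#' @param coords cell-state matrix (n x d) for one condition's cells.
#' @param expr cells x genes matrix of log-normalized expression (validated:
#'   finite, non-negative, max < 50 — raw counts are not accepted; normalize
#'   and log1p upstream). All-zero gene columns are retained but flagged.
#' @param landmarks a [select_landmarks()] object (or `NULL` to select
#'   `min(n_landmarks, n)` landmarks internally).
#' @param condition label stored with the fit.
#' @param length_scale shared kernel length-scale; `NULL` for the median
#'   heuristic on landmark distances.
#' @param amplitude kernel standard deviation; `NULL` for the pooled sd of
#'   the (gene-centered) expression values.
#' @param noise_sd shared observation noise standard deviation on the
#'   log-expression scale (default 0.3).
#' @param n_landmarks used only when `landmarks` is `NULL` (default 5000,
#'   capped at n).
#' @param jitter diagonal jitter on `K_uu` (default 1e-6).
#' @param seed seed for internal landmark selection.
#' @return object of class `kompot_expression`: `condition`, `gene_ids`,
#'   `landmarks`, `landmark_values` (m x genes posterior means at the
#'   landmarks), `landmark_cov` (shared m x m posterior covariance),
#'   and an opaque `model_state` for [impute_expression()].
#' @export
fit_expression_gp <- function(coords, expr, landmarks = NULL,
                              condition = "cond", length_scale = NULL,
                              amplitude = NULL, noise_sd = 0.3,
                              n_landmarks = 5000L, jitter = 1e-6,
                              seed = 1L) {
  coords <- check_matrix(coords)
  expr <- as.matrix(expr)
  if (nrow(expr) != nrow(coords))
    stop(sprintf("expr has %d rows but coords has %d", nrow(expr),
                 nrow(coords)))
  if (any(!is.finite(expr))) stop("expr contains non-finite values")
  if (min(expr) < 0 || max(expr) >= 50)
    stop("expr must be log-normalized: non-negative with max < 50")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  gene_ids <- colnames(expr)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(ncol(expr)))
  zero_genes <- gene_ids[colSums(expr != 0) == 0]

  if (is.null(landmarks))
    landmarks <- select_landmarks(coords, k = min(n_landmarks, nrow(coords)),
                                  seed = seed)
  stopifnot(inherits(landmarks, "kompot_landmarks"))
  Z <- landmarks$points
  if (ncol(Z) != ncol(coords))
    stop("landmark dimensionality does not match coords")

  centers <- colMeans(expr)
  Y <- sweep(expr, 2, centers)
  if (is.null(length_scale))
    length_scale <- if (nrow(Z) > 1) median_heuristic(Z) else
      median_heuristic(coords)
  if (is.null(amplitude)) amplitude <- max(sd(Y), 1e-3)

  m <- nrow(Z)
  Kuu <- matern52(Z, Z, length_scale, amplitude)
  Luu <- chol_jitter(Kuu, jitter, max_jitter = max(jitter, 1e-4))
  Kux <- matern52(Z, coords, length_scale, amplitude)
  A <- forwardsolve(Luu, Kux) / noise_sd              # m x n
  B <- diag(m) + tcrossprod(A)
  LB <- chol_jitter(B, 1e-12)

  S <- backsolve(t(LB), forwardsolve(LB, A %*% Y))    # B^-1 A Y, m x genes
  mu_u <- (Luu %*% S) / noise_sd                      # centered means at Z
  alpha <- backsolve(t(Luu), S) / noise_sd            # K_uu^-1 mu_u, m x genes
  T0 <- forwardsolve(LB, t(Luu))                      # m x m
  Sigma_u <- crossprod(T0)                            # L_uu B^-1 L_uu^T

  landmark_values <- sweep(mu_u, 2, centers, "+")
  colnames(landmark_values) <- gene_ids
  state <- list(Z = Z, Luu = Luu, LB = LB, alpha = alpha,
                centers = centers, length_scale = length_scale,
                amplitude = amplitude, noise_sd = noise_sd)
  structure(list(condition = condition, gene_ids = gene_ids,
                 landmarks = landmarks, landmark_values = landmark_values,
                 landmark_cov = Sigma_u, zero_genes = zero_genes,
                 model_state = state, n_cells = nrow(coords)),
            class = "kompot_expression")
}

#' Impute (counterfactual) expression at arbitrary cell states
#'
#' Posterior mean expression of every gene at the query states — including
#' states this condition never sampled, which is what makes cross-condition
#' counterfactual comparison possible — plus the shared per-state posterior
#' variance (uncertainty grows away from this condition's training
#' support).
#'
#' @param predictor a fitted [fit_expression_gp()].
#' @param query matrix of cell states.
#' @return list with `mean` (query x genes matrix) and `var` (per-state
#'   posterior variance, shared across genes).
#' @export
impute_expression <- function(predictor, query) {
  stopifnot(inherits(predictor, "kompot_expression"))
  st <- predictor$model_state
  query <- check_matrix(query)
  if (ncol(query) != ncol(st$Z))
    stop(sprintf("query has %d dims but the model was trained on %d",
                 ncol(query), ncol(st$Z)))
  if (nrow(query) == 0)
    return(list(mean = matrix(0, 0, length(predictor$gene_ids),
                              dimnames = list(NULL, predictor$gene_ids)),
                var = numeric(0)))
  Kqu <- matern52(query, st$Z, st$length_scale, st$amplitude)
  mu <- sweep(Kqu %*% st$alpha, 2, st$centers, "+")
  colnames(mu) <- predictor$gene_ids
  Aq <- t(forwardsolve(st$Luu, t(Kqu)))               # q x m
  Tm <- forwardsolve(st$LB, t(Aq))                    # m x q
  v <- pmax(st$amplitude^2 - rowSums(Aq^2), 0) + colSums(Tm^2)
  list(mean = mu, var = v)
}

# Full posterior covariance of the expression function at states Q (shared
# across genes): K_qq - K_qu K_uu^-1 K_uq + A_q B^-1 A_q^T. Used for
# Mahalanobis evaluation on re-selected landmark sets.
expression_posterior_cov <- function(predictor, query) {
  stopifnot(inherits(predictor, "kompot_expression"))
  st <- predictor$model_state
  query <- check_matrix(query)
  Kqq <- matern52(query, query, st$length_scale, st$amplitude)
  Kqu <- matern52(query, st$Z, st$length_scale, st$amplitude)
  Aq <- t(forwardsolve(st$Luu, t(Kqu)))
  Tm <- forwardsolve(st$LB, t(Aq))
  cov <- Kqq - tcrossprod(Aq) + crossprod(Tm)
  (cov + t(cov)) / 2
}

#' @export
print.kompot_expression <- function(x, ...) {
  cat(sprintf(
    "<kompot_expression> condition '%s': %d genes, %d cells, %d landmarks\n",
    x$condition, length(x$gene_ids), x$n_cells, x$landmarks$k))
  if (length(x$zero_genes))
    cat(sprintf("  all-zero genes: %d\n", length(x$zero_genes)))
  invisible(x)
}
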