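# Per-gene differential expression between conditions: counterfactual fold
# changes at single-cell resolution, and a covariance-aware Mahalanobis
# distance aggregating each gene's shift across a landmark set.
#
#   D(a,b) = sqrt( (mu_a - mu_b)^T (Sigma_a + Sigma_b)^-1 (mu_a - mu_b) )
#
# evaluated at landmark states, with Sigma the (gene-shared) GP posterior
# covariance. The covariance term discounts redundancy — adding a
# near-duplicate cell state contributes almost nothing — and rewards
# coordinated shifts across distinct states, so a gene moving +delta in one
# branch and -delta in another scores high even though its net fold change
# is near zero. The Methods-style quadratic form is D^2; the root is
# returned ("how many standard deviations"). D is a ranking score; no null
# distribution or multiple-testing correction is attached.

#' Per-state, per-gene counterfactual log fold change
#'
#' `lfc(x, g) = mu_b(x, g) - mu_a(x, g)`: the imputed expression under
#' condition b minus the counterfactual imputation under condition a, at
#' the same cell state — computed for every supplied state regardless of
#' which condition the cell was observed in.
#'
#' @param pred_a,pred_b fitted [fit_expression_gp()] objects with identical
#'   gene lists.
#' @param states matrix of cell states to evaluate.
#' @return states x genes matrix of natural-log fold changes.
#' @export
fold_change <- function(pred_a, pred_b, states) {
  check_gene_match(pred_a, pred_b)
  ia <- impute_expression(pred_a, states)
  ib <- impute_expression(pred_b, states)
  ib$mean - ia$mean
}

check_gene_match <- function(pred_a, pred_b) {
  stopifnot(inherits(pred_a, "kompot_expression"),
            inherits(pred_b, "kompot_expression"))
  if (!identical(pred_a$gene_ids, pred_b$gene_ids)) {
    diff <- c(setdiff(pred_a$gene_ids, pred_b$gene_ids),
              setdiff(pred_b$gene_ids, pred_a$gene_ids))
    stop("gene lists differ between predictors: ",
         paste(head(diff, 10), collapse = ", "))
  }
  invisible(TRUE)
}

#' Covariance-aware Mahalanobis distance per gene
#'
#' `D_g = sqrt( d_g^T S^-1 d_g )` for per-gene landmark mean differences
#' `d_g` and the summed posterior covariance `S = Sigma_a + Sigma_b`,
#' computed through one Cholesky factorization (with escalating jitter, up
#' to 1e-4 relative) reused for all genes — never an explicit inverse.
#'
#' @param mu_a,mu_b k x genes matrices (or length-k vectors) of landmark
#'   posterior means.
#' @param cov_sum k x k symmetric positive-(semi)definite matrix
#'   `Sigma_a + Sigma_b`.
#' @return named per-gene distances `D >= 0`.
#' @examples
#' mahalanobis_distance(c(3, 4), c(0, 0), diag(2))  # 5
#' @export
mahalanobis_distance <- function(mu_a, mu_b, cov_sum) {
  if (is.null(dim(mu_a))) mu_a <- matrix(mu_a)
  if (is.null(dim(mu_b))) mu_b <- matrix(mu_b)
  stopifnot(identical(dim(mu_a), dim(mu_b)))
  if (!isSymmetric(unname(cov_sum), tol = 1e-8))
    stop("cov_sum must be symmetric")
  if (nrow(cov_sum) != nrow(mu_a))
    stop("cov_sum dimension does not match the landmark count")
  L <- chol_jitter(unname((cov_sum + t(cov_sum)) / 2), 1e-10, 1e-4)
  diffs <- mu_a - mu_b
  w <- forwardsolve(L, diffs)
  d <- sqrt(colSums(w^2))
  names(d) <- colnames(mu_a)
  d
}

#' Compare gene expression between two conditions
#'
#' Evaluates both condition-specific expression GPs over a cell group
#' (all supplied states, or a subset via `cell_mask`), producing per-cell
#' fold changes, per-gene mean fold change, and per-gene Mahalanobis
#' distances on a landmark set re-selected from the evaluated group's
#' states (so covariance resolution tracks the group's extent).
#'
#' Per-gene calls: `significant` when `|mean_lfc| > lfc_threshold` and
#' `D > d_threshold` (defaults 0.15 and 3); `divergent` when
#' `|mean_lfc| < divergent_lfc_max` and `D > divergent_d_min` (defaults
#' 0.07 and 6) — the signature of coordinated but opposing shifts.
#'
#' @param pred_a,pred_b fitted [fit_expression_gp()] objects (comparison is
#'   a -> b; positive lfc = higher in b).
#' @param states matrix of cell states (typically all cells' states).
#' @param cell_mask optional logical/integer subset of `states` rows.
#' @param n_landmarks landmarks for the Mahalanobis evaluation (capped at
#'   the group size, with a warning when reduced; default 50).
#' @param lfc_threshold,d_threshold,divergent_lfc_max,divergent_d_min
#'   per-gene thresholds (see above).
#' @param seed seed for landmark re-selection.
#' @return object of class `kompot_de`: `gene_table` (gene_id, mean_lfc,
#'   mahalanobis, significant, category), `lfc` (states x genes within the
#'   group), `landmarks`, labels and thresholds.
#' @export
compare_expression <- function(pred_a, pred_b, states, cell_mask = NULL,
                               n_landmarks = 50L, lfc_threshold = 0.15,
                               d_threshold = 3, divergent_lfc_max = 0.07,
                               divergent_d_min = 6, seed = 1L) {
  check_gene_match(pred_a, pred_b)
  states <- check_matrix(states)
  if (!is.null(cell_mask)) {
    sub <- states[cell_mask, , drop = FALSE]
    if (nrow(sub) == 0) stop("cell_mask selects an empty subset")
  } else sub <- states
  k <- n_landmarks
  if (k > nrow(sub)) {
    warning(sprintf("n_landmarks reduced from %d to the group size %d",
                    k, nrow(sub)))
    k <- nrow(sub)
  }
  lms <- select_landmarks(sub, k = k, seed = seed)
  Z <- lms$points

  mu_a <- impute_expression(pred_a, Z)$mean
  mu_b <- impute_expression(pred_b, Z)$mean
  Sa <- expression_posterior_cov(pred_a, Z)
  Sb <- expression_posterior_cov(pred_b, Z)
  D <- mahalanobis_distance(mu_a, mu_b, Sa + Sb)

  lfc <- fold_change(pred_a, pred_b, sub)
  mean_lfc <- colMeans(lfc)

  gene_table <- data.frame(gene_id = pred_a$gene_ids,
                           mean_lfc = unname(mean_lfc),
                           mahalanobis = unname(D),
                           stringsAsFactors = FALSE)
  gene_table$significant <- abs(gene_table$mean_lfc) > lfc_threshold &
    gene_table$mahalanobis > d_threshold
  gene_table$category <- ifelse(
    abs(gene_table$mean_lfc) < divergent_lfc_max &
      gene_table$mahalanobis > divergent_d_min, "divergent",
    ifelse(!gene_table$significant, "none",
           ifelse(gene_table$mean_lfc > 0, "up", "down")))

  structure(list(condition_from = pred_a$condition,
                 condition_to = pred_b$condition,
                 gene_table = gene_table, lfc = lfc,
                 landmarks = lms,
                 thresholds = list(lfc = lfc_threshold, d = d_threshold,
                                   divergent_lfc_max = divergent_lfc_max,
                                   divergent_d_min = divergent_d_min)),
            class = "kompot_de")
}

#' Local per-state expression PTP
#'
#' The same posterior-tail-probability contract as the abundance module,
#' applied to per-state expression fold changes and the two conditions'
#' predictive standard deviations: where is a gene locally differentially
#' expressed, with what confidence.
#'
#' @param lfc states x genes fold-change matrix (or vector).
#' @param sd_a,sd_b per-state predictive standard deviations (recycled
#'   across genes).
#' @return PTP matrix shaped like `lfc`, values in `(0, 0.5]`.
#' @export
local_expression_ptp <- function(lfc, sd_a, sd_b) {
  if (is.null(dim(lfc)))
    return(posterior_tail_probability(lfc, sd_a, sd_b))
  s <- sqrt(rep_len(sd_a, nrow(lfc))^2 + rep_len(sd_b, nrow(lfc))^2)
  out <- posterior_tail_probability(as.vector(lfc), rep(s, ncol(lfc)), 0)
  matrix(out, nrow(lfc), ncol(lfc), dimnames = dimnames(lfc))
}

#' Rank genes within a differential-expression comparison
#'
#' Deterministic orderings for reporting: `up`/`down` rank by Mahalanobis
#' distance among genes passing the sign and `|mean_lfc|` criteria;
#' `divergent` ranks by distance among genes with small `|mean_lfc|`.
#' Ties break lexicographically by gene id.
#'
#' @param comparison a [compare_expression()] result.
#' @param mode one of `"up"`, `"down"`, `"divergent"`.
#' @return ordered subset of the gene table (possibly empty).
#' @export
rank_genes <- function(comparison, mode = c("up", "down", "divergent")) {
  stopifnot(inherits(comparison, "kompot_de"))
  mode <- match.arg(mode)
  tab <- comparison$gene_table
  th <- comparison$thresholds
  keep <- switch(mode,
    up = tab$mean_lfc > th$lfc & tab$mahalanobis > th$d,
    down = tab$mean_lfc < -th$lfc & tab$mahalanobis > th$d,
    divergent = abs(tab$mean_lfc) < th$divergent_lfc_max &
      tab$mahalanobis > th$divergent_d_min)
  out <- tab[keep, , drop = FALSE]
  out[order(-out$mahalanobis, out$gene_id), , drop = FALSE]
}

#' @export
print.kompot_de <- function(x, ...) {
  tab <- x$gene_table
  cat(sprintf("<kompot_de> %s -> %s, %d genes, %d landmarks\n",
              x$condition_from, x$condition_to, nrow(tab), x$landmarks$k))
  cat(sprintf("  significant: %d up, %d down; divergent: %d\n",
              sum(tab$category == "up"), sum(tab$category == "down"),
              sum(tab$category == "divergent")))
  invisible(x)
}
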