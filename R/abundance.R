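# Differential-abundance statistics between two conditions a -> b.
#
# With independent per-condition posteriors mu_a(x) +/- sigma_a(x) and
# mu_b(x) +/- sigma_b(x) for log-density (cells per volume), the density
# change at state x is delta(x) ~ N(mu_b - mu_a, sigma_a^2 + sigma_b^2).
# Cell-count normalization mu' = mu - log N turns the unit into log
# fraction of cells per volume, giving the local log-fold-change statistic
#
#   Delta(x) = mu_b(x) - mu_a(x) - log(N_a / N_b)
#
# and the posterior tail probability PTP(x) = Phi(-|Delta| / sqrt(sa^2+sb^2)),
# the probability that the true change has the opposite sign of the point
# estimate. PTPs are Bayesian posterior quantities, reported without any
# multiple-testing correction across cells.

#' Normalize a log-density to log fraction of cells per volume
#'
#' Subtracts `log(n_cells)`, making densities comparable across samples of
#' different size. Valid only when the intrinsic dimensionality used for
#' density estimation is correct for the manifold.
#'
#' @param mu per-state log-density (log cells per volume).
#' @param n_cells total cell count of the condition (`>= 1`).
#' @return `mu - log(n_cells)` elementwise.
#' @export
normalize_log_density <- function(mu, n_cells) {
  if (length(n_cells) != 1 || !is.finite(n_cells) || n_cells <= 0)
    stop("n_cells must be a single positive number")
  mu - log(n_cells)
}

#' Local density log-fold change between two conditions
#'
#' \eqn{\Delta(x) = \mu_b(x) - \mu_a(x) - \log(N_a/N_b)} (natural log),
#' antisymmetric under swapping the two conditions.
#'
#' @param mu_a,mu_b per-state log-densities of conditions a and b.
#' @param n_a,n_b total cell counts of the conditions.
#' @return per-state \eqn{\Delta}.
#' @export
log_fold_change <- function(mu_a, mu_b, n_a, n_b) {
  if (length(mu_a) != length(mu_b))
    stop(sprintf("mu_a (length %d) and mu_b (length %d) differ in length",
                 length(mu_a), length(mu_b)))
  if (n_a <= 0 || n_b <= 0) stop("cell counts must be positive")
  (mu_b - mu_a) - log(n_a / n_b)
}

#' Posterior tail probability of a Gaussian difference statistic
#'
#' \eqn{\mathrm{PTP} = \Phi(-|\Delta| / \sqrt{\sigma_a^2 + \sigma_b^2})}:
#' the posterior probability that the true change has the opposite sign of
#' the point estimate. Maximal at 0.5 (when \eqn{\Delta = 0}); decreasing
#' in \eqn{|\Delta|}; increasing in the uncertainty. Where both sds are
#' zero the limit is taken: 0 if \eqn{\Delta \ne 0}, 0.5 if
#' \eqn{\Delta = 0}.
#'
#' @param delta per-state point estimates (density or expression log-fold
#'   change).
#' @param sd_a,sd_b per-state posterior standard deviations (`>= 0`),
#'   recycled if scalar.
#' @return per-state PTP in `(0, 0.5]` (0 only in the zero-sd limit).
#' @export
posterior_tail_probability <- function(delta, sd_a, sd_b) {
  n <- length(delta)
  sd_a <- rep_len(sd_a, n)
  sd_b <- rep_len(sd_b, n)
  if (any(sd_a < 0) || any(sd_b < 0))
    stop("standard deviations must be non-negative")
  s <- sqrt(sd_a^2 + sd_b^2)
  ptp <- ifelse(s == 0, ifelse(delta == 0, 0.5, 0), pnorm(-abs(delta) / s))
  dim(ptp) <- dim(delta)
  ptp
}

#' Compare cell-state abundance between two fitted density models
#'
#' Evaluates both condition-specific density posteriors at a common set of
#' states (by default the union of both conditions' training states — every
#' cell gets a statistic, wherever it was observed) and assembles
#' \eqn{\Delta}, PTP, and significance calls.
#'
#' @param density_a,density_b fitted [fit_density()] objects; the
#'   comparison is a -> b (positive \eqn{\Delta} = more abundant in b).
#' @param states matrix of evaluation states; `NULL` for the union of both
#'   training-state sets.
#' @param cell_ids optional ids for the evaluation states.
#' @param lfc_threshold,ptp_threshold significance thresholds; defaults
#'   `|Delta| > 1`, `PTP < 1e-3`.
#' @return object of class `kompot_abundance`: a per-state table plus
#'   threshold metadata. Columns: `cell_id`, `lfc`, `ptp`,
#'   `neg_log10_ptp`, `combined_sd`, `significant`, `direction`.
#' @examples
#' \donttest{
#' ds <- make_mixture_manifold(n_per_condition = c(300, 300),
#'                             weights_a = c(0.5, 0.5),
#'                             weights_b = c(0.25, 0.75), seed = 1)
#' fa <- fit_density(ds$coords[ds$condition == "a", ], condition = "a")
#' fb <- fit_density(ds$coords[ds$condition == "b", ], condition = "b")
#' comp <- compare_abundance(fa, fb)
#' head(comp$table)
#' }
#' @export
compare_abundance <- function(density_a, density_b, states = NULL,
                              cell_ids = NULL, lfc_threshold = 1.0,
                              ptp_threshold = 1e-3) {
  stopifnot(inherits(density_a, "kompot_density"),
            inherits(density_b, "kompot_density"))
  if (is.null(states)) {
    states <- rbind(density_a$train_states, density_b$train_states)
    if (is.null(cell_ids)) cell_ids <- rownames(states)
  }
  states <- check_matrix(states)
  if (is.null(cell_ids)) cell_ids <- sprintf("state_%d", seq_len(nrow(states)))
  pa <- predict_log_density(density_a, states)
  pb <- predict_log_density(density_b, states)
  lfc <- log_fold_change(pa$mean, pb$mean, density_a$n_cells,
                         density_b$n_cells)
  ptp <- posterior_tail_probability(lfc, pa$sd, pb$sd)
  comp <- structure(
    list(condition_from = density_a$condition,
         condition_to = density_b$condition,
         table = data.frame(cell_id = cell_ids, lfc = lfc, ptp = ptp,
                            neg_log10_ptp = -log10(ptp),
                            combined_sd = sqrt(pa$sd^2 + pb$sd^2),
                            stringsAsFactors = FALSE),
         thresholds = list(lfc = lfc_threshold, ptp = ptp_threshold)),
    class = "kompot_abundance")
  classify_significance(comp, lfc_threshold, ptp_threshold)
}

#' Flag significantly shifted cell states
#'
#' A state is significant when `|lfc| > lfc_threshold` **and**
#' `ptp < ptp_threshold`; its direction follows the sign of `lfc`.
#' Defaults match the convention `|log fold change| > 1`, `PTP < 1e-3`.
#'
#' @param comparison a `kompot_abundance` object.
#' @param lfc_threshold,ptp_threshold positive thresholds.
#' @return the comparison with refreshed `significant` and `direction`
#'   columns and threshold metadata.
#' @export
classify_significance <- function(comparison, lfc_threshold = 1.0,
                                  ptp_threshold = 1e-3) {
  stopifnot(inherits(comparison, "kompot_abundance"))
  if (lfc_threshold <= 0 || ptp_threshold <= 0)
    stop("thresholds must be positive")
  tab <- comparison$table
  sig <- abs(tab$lfc) > lfc_threshold & tab$ptp < ptp_threshold
  tab$significant <- sig
  tab$direction <- ifelse(!sig, "none",
                          ifelse(tab$lfc > 0, "increase", "decrease"))
  comparison$table <- tab
  comparison$thresholds <- list(lfc = lfc_threshold, ptp = ptp_threshold)
  comparison
}

#' Summarize abundance calls by cell group
#'
#' Per annotated group (e.g. cell type): counts and fractions of
#' significant-increase, significant-decrease and non-significant states.
#' Fractions sum to 1 within each non-empty group.
#'
#' @param comparison a classified `kompot_abundance`.
#' @param groups factor-like vector aligned with the comparison's states.
#' @return data.frame with one row per group level.
#' @export
summarize_by_group <- function(comparison, groups) {
  stopifnot(inherits(comparison, "kompot_abundance"))
  tab <- comparison$table
  if (length(groups) != nrow(tab))
    stop("groups must align with the comparison's cells")
  groups <- factor(groups)
  out <- data.frame(group = levels(groups),
                    n = as.integer(table(groups)))
  cnt <- function(dir) vapply(levels(groups), function(g)
    sum(tab$direction[groups == g] == dir), integer(1))
  out$n_increase <- cnt("increase")
  out$n_decrease <- cnt("decrease")
  out$n_none <- cnt("none")
  empty <- out$n == 0
  if (any(empty))
    message("empty groups: ", paste(out$group[empty], collapse = ", "))
  denom <- ifelse(out$n == 0, NA_real_, out$n)
  out$frac_increase <- out$n_increase / denom
  out$frac_decrease <- out$n_decrease / denom
  out$frac_none <- out$n_none / denom
  out
}

#' @export
print.kompot_abundance <- function(x, ...) {
  tab <- x$table
  cat(sprintf("<kompot_abundance> %s -> %s, %d cell states\n",
              x$condition_from, x$condition_to, nrow(tab)))
  cat(sprintf("  thresholds: |lfc| > %g, PTP < %g\n",
              x$thresholds$lfc, x$thresholds$ptp))
  cat(sprintf("  significant: %d increase, %d decrease\n",
              sum(tab$direction == "increase"),
              sum(tab$direction == "decrease")))
  invisible(x)
}
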