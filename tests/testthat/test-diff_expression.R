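test_that("mahalanobis_distance: identity covariance and oracle equivalence", {
  expect_equal(unname(mahalanobis_distance(c(3, 4), c(0, 0), diag(2))), 5,
               tolerance = 1e-12)
  expect_equal(unname(mahalanobis_distance(c(1, 2), c(1, 2), diag(2))), 0)

  # explicit-inverse brute-force oracle on random SPD systems
  withr::local_seed(1)
  for (trial in 1:25) {
    k <- sample(2:20, 1)
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A) + diag(0.1, k)
    mu_a <- matrix(rnorm(k * 3), k)
    mu_b <- matrix(rnorm(k * 3), k)
    got <- mahalanobis_distance(mu_a, mu_b, S)
    d <- mu_a - mu_b
    want <- sqrt(diag(t(d) %*% solve(S) %*% d))
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
  }
  expect_error(mahalanobis_distance(c(1, 2), c(0, 0),
                                    matrix(c(1, 2, 0, 1), 2)),
               "symmetric")
})

test_that("mahalanobis_distance is invariant under joint orthogonal maps", {
  withr::local_seed(2)
  k <- 12
  S <- crossprod(matrix(rnorm(k * k), k)) + diag(0.5, k)
  v <- matrix(rnorm(k * 4), k)
  Q <- qr.Q(qr(matrix(rnorm(k * k), k)))
  d0 <- mahalanobis_distance(v, 0 * v, S)
  d1 <- mahalanobis_distance(Q %*% v, 0 * v, Q %*% S %*% t(Q))
  expect_equal(unname(d0), unname(d1), tolerance = 1e-8)
})

test_that("k = 1 Mahalanobis reduces to the abundance z-score", {
  va <- 0.7; vb <- 1.3; mu_a <- 2.5; mu_b <- 0.5
  d <- mahalanobis_distance(mu_a, mu_b, matrix(va + vb))
  expect_equal(unname(d), abs(mu_a - mu_b) / sqrt(va + vb),
               tolerance = 1e-12)
})

test_that("fold_change identity, antisymmetry, gene-list validation", {
  dat <- small_expression_data(n = 150, seed = 3)
  fit <- fit_expression_gp(dat$X, dat$expr, n_landmarks = 30, seed = 1)
  expect_equal(max(abs(fold_change(fit, fit, dat$X))), 0)

  dat_b <- small_expression_data(n = 150, seed = 4)
  fit_b <- fit_expression_gp(dat_b$X, dat_b$expr, n_landmarks = 30,
                             seed = 1, condition = "b")
  expect_equal(fold_change(fit, fit_b, dat$X),
               -fold_change(fit_b, fit, dat$X), tolerance = 1e-10)

  fit_c <- fit_b
  fit_c$gene_ids <- c("g_smooth", "other")
  expect_error(fold_change(fit, fit_c, dat$X), "other")
})

test_that("a planted additive shift is recovered locally", {
  withr::local_seed(5)
  ds <- make_mixture_manifold(c(400, 400), c(0.5, 0.5), c(0.5, 0.5),
                              seed = 6)
  ds <- plant_expression(ds, data.frame(effect = "localized_shift",
                                        delta = 1, region = 2L),
                         noise_sd = 0.1, seed = 7)
  a <- ds$condition == "a"
  pa <- fit_expression_gp(ds$coords[a, ], ds$expression[a, , drop = FALSE],
                          n_landmarks = 40, seed = 1)
  pb <- fit_expression_gp(ds$coords[!a, ], ds$expression[!a, , drop = FALSE],
                          n_landmarks = 40, seed = 1, condition = "b")
  lfc <- fold_change(pa, pb, ds$coords)
  on_region <- ds$component == 2
  expect_gt(mean(lfc[on_region, 1]), 0.8)
  expect_lt(mean(lfc[on_region, 1]), 1.2)
  expect_lt(abs(mean(lfc[!on_region, 1])), 0.2)
})

test_that("compare_expression separates planted genes from null genes", {
  res <- de_planted_run(seed = 101)
  tab <- res$gene_table
  null_d <- tab$mahalanobis[tab$effect == "null"]
  expect_gt(min(tab$mahalanobis[tab$effect != "null"]), max(null_d))
  opp <- tab$effect == "opposing_shift"
  expect_true(all(abs(tab$mean_lfc[opp]) < 0.15))
  expect_true(all(tab$mahalanobis[opp] > max(null_d)))
  # swapping conditions negates mean_lfc, keeps D
  swapped <- compare_expression(res$pred_b, res$pred_a,
                                res$dataset$coords, n_landmarks = 30,
                                seed = 2)
  expect_equal(swapped$gene_table$mean_lfc, -tab$mean_lfc,
               tolerance = 1e-8)
  expect_equal(swapped$gene_table$mahalanobis, tab$mahalanobis,
               tolerance = 1e-6)
})

test_that("near-duplicate landmarks barely change D", {
  res <- de_planted_run(seed = 102)
  Z <- res$comparison$landmarks$points
  mu_a <- impute_expression(res$pred_a, Z)$mean
  mu_b <- impute_expression(res$pred_b, Z)$mean
  Sa <- kompot:::expression_posterior_cov(res$pred_a, Z)
  Sb <- kompot:::expression_posterior_cov(res$pred_b, Z)
  d0 <- mahalanobis_distance(mu_a, mu_b, Sa + Sb)

  Zd <- rbind(Z, Z[1, ] + 1e-6)
  mu_a2 <- impute_expression(res$pred_a, Zd)$mean
  mu_b2 <- impute_expression(res$pred_b, Zd)$mean
  Sa2 <- kompot:::expression_posterior_cov(res$pred_a, Zd)
  Sb2 <- kompot:::expression_posterior_cov(res$pred_b, Zd)
  d1 <- mahalanobis_distance(mu_a2, mu_b2, Sa2 + Sb2)
  expect_true(all(abs(d1 - d0) / pmax(d0, 1e-6) < 0.01))
})

test_that("cell_mask subsetting re-selects landmarks and caps k", {
  res <- de_planted_run(seed = 103)
  mask <- res$dataset$component == 1
  sub <- compare_expression(res$pred_a, res$pred_b, res$dataset$coords,
                            cell_mask = mask, n_landmarks = 30, seed = 2)
  expect_equal(nrow(sub$lfc), sum(mask))
  # opposing genes are one-sided within a single branch
  opp <- sub$gene_table$mean_lfc[res$gene_table$effect == "opposing_shift"]
  expect_true(all(opp > 0.5))
  expect_error(compare_expression(res$pred_a, res$pred_b,
                                  res$dataset$coords,
                                  cell_mask = rep(FALSE, nrow(res$dataset$coords))),
               "empty")
  expect_warning(compare_expression(res$pred_a, res$pred_b,
                                    res$dataset$coords,
                                    cell_mask = seq_len(10),
                                    n_landmarks = 30, seed = 2),
                 "reduced")
})

test_that("local_expression_ptp mirrors the abundance PTP contract", {
  expect_equal(local_expression_ptp(0, 1, 1), 0.5)
  expect_equal(local_expression_ptp(1, 1, 0), pnorm(-1), tolerance = 1e-12)
  lfc <- matrix(rnorm(20), 5, 4)
  p <- local_expression_ptp(lfc, rep(1, 5), rep(1, 5))
  expect_equal(dim(p), dim(lfc))
  expect_equal(p, local_expression_ptp(-lfc, rep(1, 5), rep(1, 5)))
  expect_true(all(p <= 0.5 & p > 0))
})

test_that("rank_genes orders deterministically and handles empty modes", {
  res <- de_planted_run(seed = 104)
  up <- rank_genes(res$comparison, "up")
  expect_true(all(diff(up$mahalanobis) <= 0))
  expect_true(all(up$mean_lfc > res$comparison$thresholds$lfc))
  div <- rank_genes(res$comparison, "divergent")
  opp_ids <- res$gene_table$gene_id[res$gene_table$effect == "opposing_shift"]
  expect_true(all(div$gene_id %in% opp_ids))

  # permuting gene order leaves the ranked table unchanged
  perm <- res$comparison
  o <- sample(nrow(perm$gene_table))
  perm$gene_table <- perm$gene_table[o, ]
  expect_equal(rank_genes(perm, "up")$gene_id, up$gene_id)

  # all-null comparison yields empty tables under default thresholds
  null_tab <- res$comparison
  null_tab$gene_table <- subset(res$gene_table, effect == "null",
                                select = -effect)
  expect_identical(nrow(rank_genes(null_tab, "up")), 0L)
  expect_identical(nrow(rank_genes(null_tab, "down")), 0L)
  expect_identical(nrow(rank_genes(null_tab, "divergent")), 0L)
})
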