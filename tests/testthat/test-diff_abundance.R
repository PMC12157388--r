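test_that("normalize_log_density is the log-count shift", {
  expect_equal(normalize_log_density(0, 1), 0)
  expect_equal(normalize_log_density(5, exp(2)), 3)
  # duplicating the dataset (N -> 2N, mu -> mu + log 2) cancels
  mu <- c(-1.2, 0.4, 2)
  expect_equal(normalize_log_density(mu + log(2), 2 * 100),
               normalize_log_density(mu, 100))
  expect_error(normalize_log_density(1, 0), "positive")
})

test_that("log_fold_change handles size correction and antisymmetry", {
  mu <- rnorm(10)
  expect_equal(log_fold_change(mu, mu, 500, 500), rep(0, 10))
  expect_equal(log_fold_change(mu, mu, 1000, 500), rep(-log(2), 10),
               tolerance = 1e-12)
  withr::local_seed(1)
  ma <- rnorm(20); mb <- rnorm(20)
  expect_equal(log_fold_change(ma, mb, 300, 700) +
                 log_fold_change(mb, ma, 700, 300), rep(0, 20),
               tolerance = 1e-12)
  expect_error(log_fold_change(1:3, 1:4, 10, 10), "length")
})

test_that("posterior tail probability matches the normal CDF", {
  expect_equal(posterior_tail_probability(0, 1, 2), 0.5)
  expect_equal(posterior_tail_probability(1, 1, 0), pnorm(-1),
               tolerance = 1e-12)
  expect_equal(posterior_tail_probability(2, sqrt(2), sqrt(2)), pnorm(-1),
               tolerance = 1e-12)
  # degenerate zero-sd limits
  expect_equal(posterior_tail_probability(c(1, 0), 0, 0), c(0, 0.5))
  expect_error(posterior_tail_probability(1, -1, 1), "non-negative")
})

test_that("PTP is monotone and symmetric in the required ways", {
  withr::local_seed(2)
  delta <- seq(0, 5, by = 0.25)
  p <- posterior_tail_probability(delta, 1, 1)
  expect_true(all(diff(p) < 0))
  expect_true(all(p <= 0.5))
  expect_equal(p[1], 0.5)
  # increasing sd at fixed |delta| raises PTP
  sds <- seq(0.5, 4, by = 0.5)
  p2 <- vapply(sds, function(s) posterior_tail_probability(1, s, 0),
               numeric(1))
  expect_true(all(diff(p2) > 0))
  # swapping conditions leaves PTP unchanged
  d <- rnorm(30); sa <- runif(30); sb <- runif(30)
  expect_equal(posterior_tail_probability(d, sa, sb),
               posterior_tail_probability(-d, sb, sa))
})

test_that("classify_significance applies the joint default thresholds", {
  mk <- function(lfc, ptp) {
    structure(list(condition_from = "a", condition_to = "b",
                   table = data.frame(cell_id = "c1", lfc = lfc, ptp = ptp,
                                      neg_log10_ptp = -log10(ptp),
                                      combined_sd = 1),
                   thresholds = list(lfc = 1, ptp = 1e-3)),
              class = "kompot_abundance")
  }
  hit <- classify_significance(mk(1.5, 1e-4))
  expect_true(hit$table$significant)
  expect_identical(hit$table$direction, "increase")
  expect_false(classify_significance(mk(1.5, 0.01))$table$significant)
  expect_false(classify_significance(mk(-0.5, 1e-6))$table$significant)
  down <- classify_significance(mk(-1.5, 1e-6))
  expect_identical(down$table$direction, "decrease")
  expect_error(classify_significance(mk(1, 1), lfc_threshold = -1),
               "positive")
})

test_that("summarize_by_group counts directions and is permutation-invariant", {
  comp <- structure(list(
    condition_from = "a", condition_to = "b",
    table = data.frame(cell_id = paste0("c", 1:6),
                       lfc = c(2, 2, -2, 0.1, 0.2, 0),
                       ptp = c(1e-5, 1e-5, 1e-5, 0.4, 0.3, 0.5),
                       neg_log10_ptp = 1, combined_sd = 1,
                       significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                       direction = c("increase", "increase", "decrease",
                                     "none", "none", "none")),
    thresholds = list(lfc = 1, ptp = 1e-3)), class = "kompot_abundance")
  tab <- summarize_by_group(comp, rep("g1", 6))
  expect_equal(tab$frac_increase, 1 / 3)
  expect_equal(tab$frac_decrease, 1 / 6)
  expect_equal(tab$frac_none, 1 / 2)
  expect_equal(tab$frac_increase + tab$frac_decrease + tab$frac_none, 1)

  perm <- sample(6)
  comp2 <- comp
  comp2$table <- comp$table[perm, ]
  tab2 <- summarize_by_group(comp2, rep("g1", 6)[perm])
  expect_equal(tab2, tab)

  # single-group all-increase
  comp3 <- comp
  comp3$table$direction <- "increase"
  expect_equal(summarize_by_group(comp3, rep("g", 6))$frac_increase, 1)
})

test_that("compare_abundance is antisymmetric end to end", {
  withr::local_seed(3)
  ds <- make_mixture_manifold(c(300, 300), c(0.5, 0.5), c(0.3, 0.7),
                              seed = 4)
  fa <- fit_density(ds$coords[ds$condition == "a", ], intrinsic_dim = 2,
                    condition = "a", seed = 1)
  fb <- fit_density(ds$coords[ds$condition == "b", ], intrinsic_dim = 2,
                    condition = "b", seed = 2)
  ab <- compare_abundance(fa, fb, states = ds$coords)
  ba <- compare_abundance(fb, fa, states = ds$coords)
  expect_equal(ab$table$lfc, -ba$table$lfc, tolerance = 1e-10)
  expect_equal(ab$table$ptp, ba$table$ptp, tolerance = 1e-10)
  expect_true(all(ab$table$ptp <= 0.5))
  expect_true(all(ab$table$ptp > 0))
})
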