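test_that("select_landmarks: k = 1 mean, k = n identity, determinism", {
  withr::local_seed(1)
  X <- matrix(rnorm(120), 60, 2)
  one <- select_landmarks(X, k = 1, seed = 3)
  expect_equal(as.vector(one$points), colMeans(X), tolerance = 1e-12)

  all_lm <- select_landmarks(X, k = nrow(X), t = 20, seed = 3)
  got <- all_lm$points[order(all_lm$points[, 1]), ]
  want <- X[order(X[, 1]), ]
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)

  a <- select_landmarks(X, k = 8, seed = 11)
  b <- select_landmarks(X, k = 8, seed = 11)
  expect_identical(a$points, b$points)
  expect_error(select_landmarks(X, k = 100), "exceeds")
})

test_that("k-means objective is non-increasing over Lloyd iterations", {
  withr::local_seed(2)
  X <- matrix(rnorm(600), 300, 2)
  lm <- select_landmarks(X, k = 12, t = 15, seed = 5)
  expect_true(all(diff(lm$objective) <= 1e-9))
  # landmarks stay inside the data bounding box
  expect_true(all(lm$points[, 1] >= min(X[, 1]) &
                    lm$points[, 1] <= max(X[, 1])))
  expect_true(all(lm$points[, 2] >= min(X[, 2]) &
                    lm$points[, 2] <= max(X[, 2])))
})

test_that("landmark GP with k = n matches the exact GP posterior mean", {
  dat <- small_expression_data(n = 150, seed = 5)
  lms <- identity_landmarks(dat$X)
  fit <- fit_expression_gp(dat$X, dat$expr, landmarks = lms,
                           length_scale = 1, amplitude = 1, noise_sd = 0.3,
                           jitter = 1e-10)
  withr::local_seed(6)
  Xq <- matrix(runif(100, -2, 2), 50, 2)
  got <- impute_expression(fit, Xq)$mean
  want <- exact_gp_oracle(dat$X, dat$expr, Xq, 1, 1, 0.3)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("noiseless GP interpolates the training expression", {
  dat <- small_expression_data(n = 120, seed = 7)
  lms <- identity_landmarks(dat$X)
  fit <- fit_expression_gp(dat$X, dat$expr, landmarks = lms,
                           length_scale = 1, amplitude = 1,
                           noise_sd = 1e-6, jitter = 1e-12)
  got <- impute_expression(fit, dat$X)$mean
  expect_lt(max(abs(got - dat$expr)), 1e-6)
})

test_that("training residuals shrink monotonically as noise goes to zero", {
  dat <- small_expression_data(n = 100, seed = 8)
  lms <- identity_landmarks(dat$X)
  resid <- vapply(c(1, 0.3, 0.1, 0.01, 1e-3), function(s) {
    fit <- fit_expression_gp(dat$X, dat$expr, landmarks = lms,
                             length_scale = 1, amplitude = 1,
                             noise_sd = s, jitter = 1e-12)
    max(abs(impute_expression(fit, dat$X)$mean - dat$expr))
  }, numeric(1))
  expect_true(all(diff(resid) < 0))
})

test_that("constant gene columns are recovered everywhere in support", {
  withr::local_seed(9)
  X <- matrix(runif(300, -2, 2), 150, 2)
  expr <- cbind(g_const = rep(1.7, 150),
                g_var = pmax(2 + sin(X[, 1]), 0))
  fit <- fit_expression_gp(X, expr, n_landmarks = 40, noise_sd = 0.1,
                           seed = 1)
  q <- matrix(runif(60, -1.8, 1.8), 30, 2)
  got <- impute_expression(fit, q)$mean[, "g_const"]
  expect_lt(max(abs(got - 1.7)), 0.01)
})

test_that("imputation correlates with observation and flags extrapolation", {
  dat <- small_expression_data(n = 250, seed = 10, noise_sd = 0.1)
  fit <- fit_expression_gp(dat$X, dat$expr, n_landmarks = 60, seed = 1)
  imp <- impute_expression(fit, dat$X)
  expect_gt(cor(imp$mean[, "g_smooth"], dat$expr[, "g_smooth"]), 0.9)
  far <- impute_expression(fit, matrix(c(30, 30), 1))
  expect_gt(far$var, median(imp$var))
  # querying the landmarks reproduces the stored landmark values
  at_lm <- impute_expression(fit, fit$landmarks$points)
  expect_lt(max(abs(at_lm$mean - fit$landmark_values)), 1e-5)
  expect_error(impute_expression(fit, matrix(0, 2, 5)), "dims")
})

test_that("landmark covariance is symmetric PSD; inputs are validated", {
  dat <- small_expression_data(n = 150, seed = 11)
  fit <- fit_expression_gp(dat$X, dat$expr, n_landmarks = 30, seed = 1)
  S <- fit$landmark_cov
  expect_true(isSymmetric(S, tol = 1e-10))
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)

  bad <- dat$expr; bad[1, 1] <- NA
  expect_error(fit_expression_gp(dat$X, bad), "non-finite")
  expect_error(fit_expression_gp(dat$X, dat$expr - 10), "log-normalized")
  expect_error(fit_expression_gp(dat$X, dat$expr + 60), "log-normalized")
  withz <- cbind(dat$expr, g_zero = rep(0, nrow(dat$expr)))
  fitz <- fit_expression_gp(dat$X, withz, n_landmarks = 20, seed = 1)
  expect_identical(fitz$zero_genes, "g_zero")
})
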