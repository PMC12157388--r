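# Shared fixture builders. Everything is generated in code at test time;
# sizes are desk-scale so the whole suite stays inside the runtime budget.

# Small smooth 2-D dataset with expression for GP tests.
small_expression_data <- function(n = 200, seed = 5, noise_sd = 0.1) {
  withr::local_seed(seed)
  X <- matrix(runif(n * 2, -2, 2), n, 2)
  expr <- cbind(
    g_smooth = pmax(2 + sin(X[, 1]) + 0.5 * X[, 2] +
                      rnorm(n, sd = noise_sd), 0),
    g_flat = pmax(2 + cos(X[, 1]) + rnorm(n, sd = noise_sd), 0))
  list(X = X, expr = expr)
}

# Landmark set equal to the training points (for exact-GP comparisons).
identity_landmarks <- function(X) {
  structure(list(points = X, k = nrow(X), t = 0L, seed = 1L,
                 objective = numeric(0), assignment = seq_len(nrow(X))),
            class = "kompot_landmarks")
}

# Brute-force all-pairs kNN oracle (independent of the package's search).
knn_oracle <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  idx <- unname(t(apply(D, 1, function(row) order(row, seq_len(n))[seq_len(k)])))
  dist <- unname(t(vapply(seq_len(n), function(i) D[i, idx[i, ]], numeric(k))))
  list(idx = idx, dist = dist)
}

# Exact (non-landmark) GP regression posterior mean oracle, gene-centered
# like the package's model.
exact_gp_oracle <- function(X, Y, Xq, length_scale, amplitude, noise_sd) {
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  K <- kompot:::matern52(X, X, length_scale, amplitude)
  Kq <- kompot:::matern52(Xq, X, length_scale, amplitude)
  sweep(Kq %*% solve(K + diag(noise_sd^2, nrow(X)), Yc), 2, ctr, "+")
}

# One planted-effect DE run (shared by module tests and acceptance).
de_planted_run <- function(seed, n = 600, n_landmarks = 30, noise_sd = 0.1) {
  ds <- make_mixture_manifold(c(n, n), c(0.5, 0.5), c(0.5, 0.5),
                              geometry = "branches", seed = seed)
  ds <- plant_expression(
    ds, effect_table(n_null = 40, n_global = 5, n_opposing = 5, delta = 1),
    noise_sd = noise_sd, seed = seed + 1000)
  a <- ds$condition == "a"
  pa <- fit_expression_gp(ds$coords[a, ], ds$expression[a, ],
                          condition = "a", n_landmarks = n_landmarks,
                          seed = 1)
  pb <- fit_expression_gp(ds$coords[!a, ], ds$expression[!a, ],
                          condition = "b", n_landmarks = n_landmarks,
                          seed = 1)
  cmp <- compare_expression(pa, pb, ds$coords, n_landmarks = n_landmarks,
                            seed = 2)
  tab <- cmp$gene_table
  tab$effect <- ds$gene_effects$effect[match(tab$gene_id,
                                             ds$gene_effects$gene_id)]
  list(dataset = ds, pred_a = pa, pred_b = pb, comparison = cmp,
       gene_table = tab)
}
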