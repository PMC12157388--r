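# Synthetic multi-condition single-cell datasets with analytic ground
# truth: manifold geometry (Gaussian mixture or branching curves),
# condition-specific abundance shifts via mixture weights, and planted
# per-gene expression effects. A statistical test double for real data —
# not a count simulator: expression noise is Gaussian on the log scale
# (an optional negative-binomial count layer exists for integration tests).

#' Generate a two-condition mixture manifold with known densities
#'
#' Cells for each condition are drawn from a shared set of components with
#' condition-specific mixture weights, so the true per-condition density
#' (cells per volume, `N_c` times the mixture pdf) — and hence the true
#' abundance log-fold change — is available analytically at every cell.
#'
#' Geometries: `"mixture"` — isotropic Gaussian blobs at `centers`;
#' `"branches"` — line segments from the origin with Gaussian cross-section
#' noise (for branch-specific expression effects), true density computed by
#' 1-D quadrature along each branch.
#'
#' @param n_per_condition integer vector of cells per condition (length 2,
#'   conditions "a" and "b").
#' @param weights_a,weights_b component weights per condition (simplex
#'   vectors of equal length; they are normalized if needed).
#' @param centers components x dims matrix of component centers (mixture
#'   geometry) or branch endpoint directions (branches geometry). Default:
#'   2 components in 2-D separated by 6 sd.
#' @param sd component standard deviation (mixture) or branch cross-section
#'   noise sd (branches). Default 1 (mixture), 0.1 (branches).
#' @param geometry `"mixture"` or `"branches"`.
#' @param seed RNG seed; the dataset is bit-reproducible from it.
#' @return object of class `kompot_dataset`: `coords`, `cell_ids`,
#'   `condition`, `component` (factor, the generating component/branch),
#'   `true_log_density` (cells x conditions, log cells per volume),
#'   `weights`, `geometry`, `seed`; expression slots filled by
#'   [plant_expression()].
#' @examples
#' ds <- make_mixture_manifold(c(200, 200), c(0.5, 0.5), c(0.25, 0.75),
#'                             seed = 7)
#' table(ds$condition, ds$component)
#' @export
make_mixture_manifold <- function(n_per_condition = c(500L, 500L),
                                  weights_a = c(0.5, 0.5),
                                  weights_b = c(0.5, 0.5),
                                  centers = NULL, sd = NULL,
                                  geometry = c("mixture", "branches"),
                                  seed = 1L) {
  geometry <- match.arg(geometry)
  if (length(weights_a) != length(weights_b))
    stop("weights_a and weights_b must have equal length")
  if (any(weights_a < 0) || any(weights_b < 0))
    stop("mixture weights must be non-negative")
  weights_a <- weights_a / sum(weights_a)
  weights_b <- weights_b / sum(weights_b)
  n_comp <- length(weights_a)
  if (length(n_per_condition) != 2)
    stop("n_per_condition must give cell counts for exactly 2 conditions")
  if (is.null(centers)) {
    if (geometry == "mixture") {
      centers <- cbind(6 * (seq_len(n_comp) - 1), 0)
    } else {
      ang <- pi / 2 + (seq_len(n_comp) - 1) * (2 * pi / max(n_comp, 3))
      centers <- 5 * cbind(cos(ang), sin(ang))
    }
  }
  centers <- check_matrix(centers)
  if (nrow(centers) != n_comp)
    stop("centers must have one row per mixture component")
  if (is.null(sd)) sd <- if (geometry == "mixture") 1 else 0.1
  p <- ncol(centers)
  n_a <- n_per_condition[1]; n_b <- n_per_condition[2]

  sim <- with_seed(seed, {
    comp_a <- sample.int(n_comp, n_a, replace = TRUE, prob = weights_a)
    comp_b <- sample.int(n_comp, n_b, replace = TRUE, prob = weights_b)
    comp <- c(comp_a, comp_b)
    n <- n_a + n_b
    if (geometry == "mixture") {
      coords <- centers[comp, , drop = FALSE] +
        matrix(rnorm(n * p, sd = sd), n, p)
    } else {
      pos <- runif(n)  # arc-length position along the branch
      coords <- centers[comp, , drop = FALSE] * pos +
        matrix(rnorm(n * p, sd = sd), n, p)
    }
    list(coords = coords, comp = comp)
  })
  coords <- sim$coords
  component <- factor(sim$comp)
  condition <- factor(rep(c("a", "b"), c(n_a, n_b)))
  cell_ids <- sprintf("cell_%04d", seq_len(n_a + n_b))
  dimnames(coords) <- list(cell_ids, sprintf("dim_%d", seq_len(p)))

  dens <- function(w, n_cells) {
    if (geometry == "mixture") {
      pdf <- rep(0, nrow(coords))
      for (jj in seq_len(n_comp)) {
        d2 <- rowSums(sweep(coords, 2, centers[jj, ])^2)
        pdf <- pdf + w[jj] * exp(-d2 / (2 * sd^2)) / (2 * pi * sd^2)^(p / 2)
      }
      log(n_cells) + log(pdf)
    } else {
      # branch density: uniform along the segment x isotropic Gaussian
      # cross-section, integrated over arc position by quadrature
      ts <- seq(0, 1, length.out = 201)
      pdf <- rep(0, nrow(coords))
      for (jj in seq_len(n_comp)) {
        len <- sqrt(sum(centers[jj, ]^2))
        f <- vapply(ts, function(tt) {
          d2 <- rowSums(sweep(coords, 2, centers[jj, ] * tt)^2)
          exp(-d2 / (2 * sd^2)) / (2 * pi * sd^2)^(p / 2)
        }, numeric(nrow(coords)))
        pdf <- pdf + w[jj] * rowMeans(f) / 1  # density per unit t, t~U(0,1)
      }
      log(n_cells) + log(pdf)
    }
  }
  tld <- cbind(a = dens(weights_a, n_a), b = dens(weights_b, n_b))
  rownames(tld) <- cell_ids

  structure(list(coords = coords, cell_ids = cell_ids, condition = condition,
                 component = component, true_log_density = tld,
                 weights = list(a = weights_a, b = weights_b),
                 centers = centers, sd = sd, geometry = geometry,
                 seed = as.integer(seed), expression = NULL,
                 gene_effects = NULL),
            class = "kompot_dataset")
}

#' Plant gene-expression effects on a synthetic manifold
#'
#' Baseline expression of each gene is a smooth random function of the
#' latent position (a random affine form squashed through a sigmoid, scaled
#' and offset so values stay in the log1p-normalized range) plus Gaussian
#' noise. Condition-b cells then receive per-gene effects:
#'
#' * `null` — no effect;
#' * `global_shift` — `+delta` everywhere;
#' * `localized_shift` — `+delta` on cells of component `region`;
#' * `opposing_shift` — `+delta` on component 1, `-delta` on component 2
#'   (zero net change when branches are balanced).
#'
#' @param dataset a [make_mixture_manifold()] result.
#' @param effects data.frame with columns `effect` (one of the four kinds),
#'   `delta` (ignored for null), and optional `region` (component index for
#'   localized shifts); one row per gene. See [effect_table()].
#' @param noise_sd Gaussian noise sd on the log-expression scale
#'   (default 0.1).
#' @param baseline_offset additive offset keeping expression positive under
#'   negative effects (default 2).
#' @param seed RNG seed (independent of the geometry seed).
#' @return the dataset with `expression` (cells x genes, non-negative log
#'   scale) and `gene_effects` (the descriptor table with gene ids) filled.
#' @export
plant_expression <- function(dataset, effects, noise_sd = 0.1,
                             baseline_offset = 2, seed = 1L) {
  stopifnot(inherits(dataset, "kompot_dataset"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  effects <- as.data.frame(effects)
  if (!"effect" %in% names(effects)) stop("effects needs an 'effect' column")
  bad <- setdiff(effects$effect,
                 c("null", "global_shift", "localized_shift",
                   "opposing_shift"))
  if (length(bad)) stop("unknown effect kinds: ", paste(bad, collapse = ", "))
  if (is.null(effects$delta)) effects$delta <- 0
  if (is.null(effects$region)) effects$region <- 1L
  n_genes <- nrow(effects)
  coords <- dataset$coords
  n <- nrow(coords)
  p <- ncol(coords)
  is_b <- dataset$condition == "b"
  comp <- as.integer(dataset$component)

  expr <- with_seed(seed, {
    E <- matrix(0, n, n_genes)
    scale01 <- function(x) (x - min(x)) / max(max(x) - min(x), 1e-12)
    for (g in seq_len(n_genes)) {
      w <- rnorm(p)
      b0 <- rnorm(1)
      s_g <- runif(1, 0.5, 2.5)
      base <- baseline_offset +
        s_g * plogis(scale01(as.vector(coords %*% w)) * 4 - 2 + b0)
      eff <- rep(0, n)
      dl <- effects$delta[g]
      eff_b <- switch(effects$effect[g],
        null = 0,
        global_shift = dl,
        localized_shift = ifelse(comp == effects$region[g], dl, 0),
        opposing_shift = ifelse(comp == 1L, dl,
                                ifelse(comp == 2L, -dl, 0)))
      eff[is_b] <- if (length(eff_b) == 1) eff_b else eff_b[is_b]
      E[, g] <- pmax(base + eff + rnorm(n, sd = noise_sd), 0)
    }
    E
  })
  gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
  colnames(expr) <- gene_ids
  rownames(expr) <- dataset$cell_ids
  effects$gene_id <- gene_ids
  dataset$expression <- expr
  dataset$gene_effects <- effects[, c("gene_id", "effect", "delta", "region")]
  dataset$expression_seed <- as.integer(seed)
  dataset$noise_sd <- noise_sd
  dataset
}

#' Build a per-gene effect descriptor table
#'
#' @param n_null,n_global,n_localized,n_opposing gene counts per effect
#'   kind.
#' @param delta effect size for the non-null kinds (natural-log scale).
#' @param region component receiving localized shifts.
#' @return data.frame consumable by [plant_expression()]; non-null genes
#'   come first.
#' @export
effect_table <- function(n_null = 40, n_global = 0, n_localized = 0,
                         n_opposing = 0, delta = 1, region = 1L) {
  data.frame(
    effect = c(rep("global_shift", n_global),
               rep("localized_shift", n_localized),
               rep("opposing_shift", n_opposing),
               rep("null", n_null)),
    delta = c(rep(delta, n_global + n_localized + n_opposing),
              rep(0, n_null)),
    region = region,
    stringsAsFactors = FALSE)
}

#' Optional negative-binomial count layer (integration tests only)
#'
#' Converts log-scale expression to counts via `rnbinom` with mean
#' `expm1(expression)` and the given dispersion, then back through
#' `log1p`. This is *not* a realistic scRNA-seq simulator (no library-size
#' or dropout structure); it only exercises the pipeline's tolerance to
#' count-derived input.
#'
#' @param dataset a dataset with planted expression.
#' @param dispersion negative-binomial size parameter.
#' @param seed RNG seed.
#' @return cells x genes matrix of `log1p` counts.
#' @export
as_count_layer <- function(dataset, dispersion = 10, seed = 1L) {
  stopifnot(inherits(dataset, "kompot_dataset"),
            !is.null(dataset$expression))
  mu <- expm1(dataset$expression)
  cnt <- with_seed(seed, matrix(
    rnbinom(length(mu), size = dispersion, mu = as.vector(mu)),
    nrow(mu), ncol(mu), dimnames = dimnames(mu)))
  log1p(cnt)
}

#' @export
print.kompot_dataset <- function(x, ...) {
  cat(sprintf("<kompot_dataset> %s geometry, %d cells (%s), %d components\n",
              x$geometry, nrow(x$coords),
              paste(sprintf("%s: %d", levels(x$condition),
                            table(x$condition)), collapse = ", "),
              nlevels(x$component)))
  if (!is.null(x$expression))
    cat(sprintf("  expression: %d genes (%s)\n", ncol(x$expression),
                paste(sprintf("%s: %d",
                              names(table(x$gene_effects$effect)),
                              table(x$gene_effects$effect)),
                      collapse = ", ")))
  invisible(x)
}

#' Write a synthetic dataset as a plain-text fixture bundle
#'
#' Directory layout: `coords.tsv` (cell_id + latent dims),
#' `metadata.tsv` (cell_id, condition, component, true log-densities),
#' `expression.tsv` (dense, full precision) plus `genes.tsv`,
#' `gene_effects.tsv`, and `dataset.json` (generator parameters). Numeric
#' values round-trip through [read_fixture()] to 1e-12 (17 significant
#' digits).
#'
#' @param dataset a `kompot_dataset`.
#' @param path directory to create.
#' @param format only `"csv"` (TSV bundle) is supported.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(dataset, path, format = "csv") {
  stopifnot(inherits(dataset, "kompot_dataset"))
  if (!identical(format, "csv"))
    stop(sprintf("unsupported fixture format '%s'", format))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  co <- data.frame(cell_id = dataset$cell_ids, dataset$coords,
                   check.names = FALSE)
  colnames(co)[-1] <- sprintf("dim_%d", seq_len(ncol(dataset$coords)))
  write_tsv_precise(co, file.path(path, "coords.tsv"))
  md <- data.frame(cell_id = dataset$cell_ids,
                   condition = as.character(dataset$condition),
                   component = as.character(dataset$component),
                   true_log_density_a = dataset$true_log_density[, "a"],
                   true_log_density_b = dataset$true_log_density[, "b"],
                   stringsAsFactors = FALSE)
  write_tsv_precise(md, file.path(path, "metadata.tsv"))
  if (!is.null(dataset$expression)) {
    ex <- data.frame(cell_id = dataset$cell_ids, dataset$expression,
                     check.names = FALSE)
    write_tsv_precise(ex, file.path(path, "expression.tsv"))
    write_tsv_precise(data.frame(gene_id = colnames(dataset$expression)),
                      file.path(path, "genes.tsv"))
    write_tsv_precise(dataset$gene_effects,
                      file.path(path, "gene_effects.tsv"))
  }
  meta <- list(kind = "kompot_fixture", geometry = dataset$geometry,
               seed = dataset$seed, sd = dataset$sd,
               weights = dataset$weights,
               centers = dataset$centers,
               expression_seed = dataset$expression_seed,
               noise_sd = dataset$noise_sd)
  jsonlite::write_json(meta, file.path(path, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a fixture bundle written by [write_fixture()]
#'
#' @param path fixture directory.
#' @return a `kompot_dataset` equal (to 1e-12) to the one written.
#' @export
read_fixture <- function(path) {
  jpath <- file.path(path, "dataset.json")
  if (!file.exists(jpath))
    stop(sprintf("'%s' is not a kompot fixture (missing dataset.json)",
                 path))
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  co <- read_tsv_plain(file.path(path, "coords.tsv"))
  md <- read_tsv_plain(file.path(path, "metadata.tsv"))
  if (!identical(co$cell_id, md$cell_id))
    stop("coords.tsv and metadata.tsv disagree on cell ids")
  coords <- as.matrix(co[, -1, drop = FALSE])
  rownames(coords) <- co$cell_id
  tld <- cbind(a = md$true_log_density_a, b = md$true_log_density_b)
  rownames(tld) <- md$cell_id
  ds <- structure(list(coords = coords, cell_ids = co$cell_id,
                       condition = factor(md$condition),
                       component = factor(md$component),
                       true_log_density = tld,
                       weights = meta$weights,
                       centers = if (!is.null(meta$centers))
                         as.matrix(meta$centers) else NULL,
                       sd = meta$sd, geometry = meta$geometry,
                       seed = meta$seed, expression = NULL,
                       gene_effects = NULL),
                  class = "kompot_dataset")
  epath <- file.path(path, "expression.tsv")
  if (file.exists(epath)) {
    ex <- read_tsv_plain(epath)
    expr <- as.matrix(ex[, -1, drop = FALSE])
    rownames(expr) <- ex$cell_id
    ds$expression <- expr
    ds$gene_effects <- read_tsv_plain(file.path(path, "gene_effects.tsv"))
    ds$expression_seed <- meta$expression_seed
    ds$noise_sd <- meta$noise_sd
  }
  ds
}
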