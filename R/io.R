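# Readers/writers for plain-text single-cell inputs, run configuration,
# and the end-to-end pipeline. Models are serialized with saveRDS (R's
# native archive format); tables are TSV with full-precision numerics so
# reruns are byte-identical.

#' Default run configuration
#'
#' Threshold defaults: differential abundance `|lfc| > 1`, `PTP < 1e-3`;
#' differential expression `|mean_lfc| > 0.15`, `D > 3`; divergent genes
#' `|mean_lfc| < 0.07`, `D > 6`.
#'
#' @param ... overrides of any default field (unknown names are an error).
#' @return object of class `kompot_config` (a validated named list).
#' @export
kompot_config <- function(...) {
  defaults <- list(
    input = NULL, coords_file = NULL, metadata_file = NULL,
    expression_file = NULL, genes_file = NULL,
    embedding_slot = "latent", condition_column = "condition",
    conditions = NULL, annotation_column = NULL,
    n_components = 10L, n_neighbors = 30L, alpha = 1,
    scale_by_eigenvalues = FALSE, use_diffusion = TRUE,
    intrinsic_dim = NULL, density_ls_mult = 6,
    n_landmarks = 5000L, kmeans_iters = 10L,
    expression_noise_sd = 0.3,
    de_n_landmarks = 50L,
    da_lfc_threshold = 1.0, da_ptp_threshold = 1e-3,
    de_lfc_threshold = 0.15, de_d_threshold = 3,
    divergent_lfc_max = 0.07, divergent_d_min = 6,
    out_prefix = ".", seed = 1L, verbose = TRUE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, dots, keep.null = TRUE)
  for (f in c("da_lfc_threshold", "da_ptp_threshold", "de_lfc_threshold",
              "de_d_threshold", "divergent_lfc_max", "divergent_d_min"))
    if (cfg[[f]] <= 0) stop(sprintf("config field '%s' must be positive", f))
  structure(cfg, class = "kompot_config")
}

#' Write / read a configuration file (JSON)
#'
#' Round-trips with full fidelity; unknown fields are rejected on read.
#'
#' @param config a `kompot_config`.
#' @param path file path.
#' @return `path` / the restored `kompot_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "kompot_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(kompot_config, vals)
}

#' Read a dataset into a validated latent embedding
#'
#' Accepts either a fixture directory written by [write_fixture()] or an
#' explicit bundle of plain-text files: a coordinate table (TSV/CSV with a
#' `cell_id` column), a metadata table carrying the condition column, and
#' optionally dense-TSV or MatrixMarket expression with a gene list.
#'
#' @param path fixture directory (or `NULL` when giving explicit files).
#' @param config a [kompot_config()] naming the files/columns.
#' @return list with `embedding` (a [latent_embedding()]) and `expression`
#'   (cells x genes matrix or `NULL`).
#' @export
read_dataset <- function(path = NULL, config = kompot_config()) {
  if (!is.null(path) && dir.exists(path) &&
      file.exists(file.path(path, "dataset.json"))) {
    ds <- read_fixture(path)
    ann <- data.frame(component = ds$component)
    emb <- latent_embedding(ds$coords, ds$cell_ids, ds$condition, ann)
    return(list(embedding = emb, expression = ds$expression))
  }
  cf <- config$coords_file
  mf <- config$metadata_file
  if (is.null(cf) || is.null(mf))
    stop("read_dataset needs a fixture directory or coords_file + metadata_file")
  sep_of <- function(f) if (grepl("\\.csv$", f)) "," else "\t"
  co <- read.table(cf, sep = sep_of(cf), header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  md <- read.table(mf, sep = sep_of(mf), header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!"cell_id" %in% names(co)) stop("coords file needs a 'cell_id' column")
  if (!"cell_id" %in% names(md)) stop("metadata file needs a 'cell_id' column")
  missing_ids <- setdiff(co$cell_id, md$cell_id)
  if (length(missing_ids))
    stop("cell ids present in coords but missing from metadata: ",
         paste(head(missing_ids, 5), collapse = ", "))
  md <- md[match(co$cell_id, md$cell_id), , drop = FALSE]
  cc <- config$condition_column
  if (!cc %in% names(md))
    stop(sprintf("metadata is missing the condition column '%s'", cc))
  coords <- as.matrix(co[, setdiff(names(co), "cell_id"), drop = FALSE])
  ann_cols <- setdiff(names(md), c("cell_id", cc))
  ann <- if (length(ann_cols)) md[, ann_cols, drop = FALSE] else NULL
  emb <- latent_embedding(coords, co$cell_id, md[[cc]], ann)

  expression <- NULL
  ef <- config$expression_file
  if (!is.null(ef)) {
    if (grepl("\\.mtx$", ef)) {
      gf <- config$genes_file
      if (is.null(gf)) stop("MTX expression requires genes_file")
      genes <- read.table(gf, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
      M <- as.matrix(Matrix::readMM(ef))
      if (nrow(M) == length(emb$cell_ids) && ncol(M) == nrow(genes)) {
        expression <- M
      } else if (ncol(M) == length(emb$cell_ids) && nrow(M) == nrow(genes)) {
        expression <- t(M)  # genes x cells orientation
      } else {
        stop(sprintf("MTX is %d x %d but there are %d cells and %d genes",
                     nrow(M), ncol(M), length(emb$cell_ids), nrow(genes)))
      }
      colnames(expression) <- genes[[1]]
      rownames(expression) <- emb$cell_ids
    } else {
      ex <- read_tsv_plain(ef)
      expression <- as.matrix(ex[, -1, drop = FALSE])
      rownames(expression) <- ex$cell_id
      expression <- expression[emb$cell_ids, , drop = FALSE]
    }
  }
  list(embedding = emb, expression = expression)
}

#' Write an abundance comparison as TSV
#'
#' Columns: cell_id, condition_from, condition_to, lfc, ptp,
#' neg_log10_ptp, significant, direction.
#'
#' @param comparison a `kompot_abundance`.
#' @param path output file.
#' @export
write_abundance <- function(comparison, path) {
  stopifnot(inherits(comparison, "kompot_abundance"))
  tab <- comparison$table
  out <- data.frame(cell_id = tab$cell_id,
                    condition_from = comparison$condition_from,
                    condition_to = comparison$condition_to,
                    lfc = tab$lfc, ptp = tab$ptp,
                    neg_log10_ptp = tab$neg_log10_ptp,
                    significant = tab$significant,
                    direction = tab$direction,
                    stringsAsFactors = FALSE)
  write_tsv_precise(out, path)
}

#' Write a differential-expression gene table as TSV
#'
#' @param comparison a `kompot_de`.
#' @param path output file.
#' @export
write_de_table <- function(comparison, path) {
  stopifnot(inherits(comparison, "kompot_de"))
  write_tsv_precise(comparison$gene_table, path)
}

#' Run the full comparison pipeline
#'
#' embed -> per-condition density -> differential abundance (all ordered
#' condition pairs) -> per-condition expression GPs -> differential
#' expression. Deterministic given `config$seed` (each stage derives its
#' own sub-seed). A machine-readable `manifest.json` is always written,
#' recording versions, configuration, seed and — on failure — the failing
#' stage.
#'
#' @param config a [kompot_config()]; `input` (fixture dir) or explicit
#'   file fields must be set, and `out_prefix` names the output directory.
#' @return invisible list of in-memory results (`diffmap`, `densities`,
#'   `da`, `expression`, `de`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "kompot_config"))
  out_dir <- config$out_prefix
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "kompot",
                   version = as.character(utils::packageVersion("kompot")),
                   r_version = R.version.string,
                   seed = config$seed, status = "running", stage = NULL,
                   config = unclass(config))
  write_manifest <- function() {
    manifest$timestamp <- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  stage <- "read"
  res <- tryCatch({
    dat <- read_dataset(config$input, config)
    emb <- dat$embedding
    conds <- config$conditions
    if (is.null(conds)) conds <- levels(emb$condition)
    if (!all(conds %in% levels(emb$condition)))
      stop("conditions not present in the data: ",
           paste(setdiff(conds, levels(emb$condition)), collapse = ", "))
    if (length(conds) < 2) stop("at least 2 conditions are required")

    stage <- "embed"
    if (isTRUE(config$use_diffusion)) {
      dm <- compute_diffusion_map(emb, config$n_components,
                                  config$n_neighbors, config$alpha,
                                  config$scale_by_eigenvalues)
      states <- dm$coords
      write_tsv_precise(data.frame(cell_id = emb$cell_ids, states,
                                   check.names = FALSE),
                        file.path(out_dir, "diffusion_coords.tsv"))
    } else {
      dm <- NULL
      states <- emb$coords
    }

    stage <- "density"
    d_hat <- config$intrinsic_dim
    if (is.null(d_hat)) d_hat <- estimate_intrinsic_dimension(states)
    densities <- list()
    for (cn in conds) {
      sel <- emb$condition == cn
      densities[[cn]] <- fit_density(
        states[sel, , drop = FALSE], intrinsic_dim = d_hat, condition = cn,
        ls_mult = config$density_ls_mult,
        n_landmarks = config$n_landmarks,
        seed = derive_seed(config$seed, paste0("density_", cn)))
      saveRDS(densities[[cn]],
              file.path(out_dir, sprintf("density_%s.rds", cn)))
    }

    stage <- "da"
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    da <- list()
    for (pr in pairs) {
      cmp <- compare_abundance(densities[[pr[1]]], densities[[pr[2]]],
                               states = states, cell_ids = emb$cell_ids,
                               lfc_threshold = config$da_lfc_threshold,
                               ptp_threshold = config$da_ptp_threshold)
      key <- paste(pr, collapse = "_to_")
      da[[key]] <- cmp
      write_abundance(cmp, file.path(out_dir, sprintf("da_%s.tsv", key)))
    }

    expression <- NULL
    de <- NULL
    if (!is.null(dat$expression)) {
      stage <- "expression"
      expression <- list()
      for (cn in conds) {
        sel <- emb$condition == cn
        expression[[cn]] <- fit_expression_gp(
          states[sel, , drop = FALSE],
          dat$expression[sel, , drop = FALSE],
          condition = cn, noise_sd = config$expression_noise_sd,
          n_landmarks = config$n_landmarks,
          seed = derive_seed(config$seed, paste0("expression_", cn)))
        saveRDS(expression[[cn]],
                file.path(out_dir, sprintf("expression_%s.rds", cn)))
      }
      stage <- "de"
      de <- list()
      for (pr in pairs) {
        key <- paste(pr, collapse = "_to_")
        cmp <- compare_expression(
          expression[[pr[1]]], expression[[pr[2]]], states,
          n_landmarks = config$de_n_landmarks,
          lfc_threshold = config$de_lfc_threshold,
          d_threshold = config$de_d_threshold,
          divergent_lfc_max = config$divergent_lfc_max,
          divergent_d_min = config$divergent_d_min,
          seed = derive_seed(config$seed, "landmarks"))
        de[[key]] <- cmp
        write_de_table(cmp, file.path(out_dir, sprintf("de_%s.tsv", key)))
      }
    }
    stage <- "done"
    list(diffmap = dm, densities = densities, da = da,
         expression = expression, de = de, paths = out_dir)
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$stage <<- stage
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  manifest$status <- "ok"
  manifest$stage <- "done"
  cfg_path <- file.path(out_dir, "config.json")
  write_config(config, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  write_manifest()
  invisible(res)
}
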