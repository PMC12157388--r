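#' Construct a validated latent embedding of co-embedded cells
#'
#' The entry container for all downstream analysis: a cells-by-dimensions
#' matrix of batch-corrected latent coordinates shared across conditions,
#' plus a condition label per cell. kompot assumes conditions are already
#' co-embedded and corrected; it performs no integration itself.
#'
#' @param coords numeric matrix, cells x latent dimensions.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @param condition vector (coerced to factor) of condition labels per cell.
#' @param annotations optional data.frame of per-cell categorical columns
#'   (cell type, group) aligned with `cell_ids`.
#' @return object of class `kompot_embedding` with elements `coords`
#'   (rownames = cell ids), `cell_ids`, `condition`, `annotations`.
#' @examples
#' emb <- latent_embedding(matrix(rnorm(20), 10, 2),
#'                         cell_ids = paste0("c", 1:10),
#'                         condition = rep(c("a", "b"), each = 5))
#' emb
#' @export
latent_embedding <- function(coords, cell_ids = rownames(coords), condition,
                             annotations = NULL) {
  coords <- check_matrix(coords, "coords")
  n <- nrow(coords)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(n))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n)
    stop(sprintf("cell_ids has length %d but coords has %d rows",
                 length(cell_ids), n))
  if (anyDuplicated(cell_ids)) {
    dup <- unique(cell_ids[duplicated(cell_ids)])
    stop("duplicate cell ids: ", paste(head(dup, 5), collapse = ", "))
  }
  if (length(condition) != n)
    stop("condition must have one label per cell")
  condition <- factor(condition)
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (nrow(annotations) != n)
      stop("annotations must have one row per cell")
    rownames(annotations) <- cell_ids
  }
  rownames(coords) <- cell_ids
  structure(list(coords = coords, cell_ids = cell_ids,
                 condition = condition, annotations = annotations),
            class = "kompot_embedding")
}

#' @export
print.kompot_embedding <- function(x, ...) {
  cat(sprintf("<kompot_embedding> %d cells x %d latent dims\n",
              nrow(x$coords), ncol(x$coords)))
  cat("conditions:",
      paste(sprintf("%s (%d)", levels(x$condition), table(x$condition)),
            collapse = ", "), "\n")
  invisible(x)
}

# Subset an embedding to the cells of one condition.
embedding_subset <- function(embedding, condition) {
  keep <- embedding$condition == condition
  if (!any(keep))
    stop(sprintf("no cells with condition '%s'", condition))
  latent_embedding(embedding$coords[keep, , drop = FALSE],
                   embedding$cell_ids[keep],
                   droplevels(embedding$condition[keep]),
                   if (!is.null(embedding$annotations))
                     embedding$annotations[keep, , drop = FALSE])
}
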