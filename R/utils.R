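# Internal helpers: seeded RNG scoping, argument checks, formatting.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a global seed; keeps results < 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, embed = 23L, density_a = 37L, density_b = 41L,
               expression_a = 53L, expression_b = 59L, landmarks = 67L,
               de = 71L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop(sprintf("'%s' must be a numeric matrix", name))
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name))
  x
}

# Squared Euclidean cross-distances, clamped at zero against round-off.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Full-precision numeric formatting for byte-stable on-disk tables.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_precise <- function(df, path) {
  is_num <- vapply(df, is.double, logical(1))
  out <- df
  out[is_num] <- lapply(df[is_num], fmt_num)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "")
}

log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}
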