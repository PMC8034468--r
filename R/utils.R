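# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Resolve a sample subset against the columns of an expression matrix.
resolve_samples <- function(mat, samples) {
  if (is.null(samples)) return(colnames(mat))
  samples <- as.character(samples)
  missing <- setdiff(samples, colnames(mat))
  if (length(missing) > 0) {
    stop("samples not present in matrix: ", paste(missing, collapse = ", "))
  }
  samples
}

# Canonical unordered key for a gene pair, used to match pair sets.
pair_key <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\r")
}

empty_pairs <- function(extra = character()) {
  cols <- c("gene_a", "gene_b", extra)
  out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
  names(out) <- cols
  out$gene_a <- character(0)
  out$gene_b <- character(0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
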