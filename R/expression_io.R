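#' Read a gene-by-sample expression table
#'
#' Reads a delimited text file with gene identifiers in the first column and
#' sample identifiers in the header row. Cells must be nonnegative numbers or
#' empty; empty cells (and literal `NA`) denote genes that were not measured in
#' that sample and become `NA` in the returned matrix. A measured zero is kept
#' as `0` and is distinct from `NA`: zeros participate in the evaluability
#' rules of the REO machinery, unmeasured genes do not.
#'
#' @param path Path to the file.
#' @param sep Field delimiter. When `NULL` (default) it is inferred from the
#'   file extension: `"\t"` for `.tsv`/`.txt`, `","` for `.csv`.
#' @return A numeric matrix (genes in rows, samples in columns) with unique
#'   `rownames` (gene ids) and `colnames` (sample ids); `NA` marks unmeasured
#'   entries.
#' @seealso [write_expression_table()], [map_gene_ids()]
#' @export
read_expression_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% infer_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected a gene-id column plus at least one sample column")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (anyDuplicated(genes)) {
    stop("duplicated gene rows: ", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicated sample ids: ", paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  vals[trimws(vals) == ""] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("malformed numeric cell at gene '%s', sample '%s': '%s'",
                 genes[bad[1, 1]], samples[bad[1, 2]], vals[bad[1, 1], bad[1, 2]]))
  }
  num[!is.na(vals) & vals == "NA"] <- NA_real_
  dimnames(num) <- list(genes, samples)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to a delimited text file
#'
#' Inverse of [read_expression_table()]: `NA` entries are written as empty
#' cells so that a read/write/read cycle round-trips numeric values exactly
#' (values are written with full double precision).
#'
#' @param mat Expression matrix as returned by [read_expression_table()].
#' @param path Output path.
#' @param sep Field delimiter; inferred from the extension when `NULL`.
#' @param gene_column Name for the gene-id column header.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(mat, path, sep = NULL, gene_column = "gene_id") {
  validate_expression_matrix(mat)
  sep <- sep %||% infer_sep(path)
  txt <- format(mat, digits = 17, trim = TRUE, scientific = FALSE)
  txt[is.na(mat)] <- ""
  out <- cbind(rownames(mat), txt)
  colnames(out) <- c(gene_column, colnames(mat))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Validate an expression matrix
#'
#' Checks the container invariants assumed throughout the package: a numeric
#' matrix with unique gene and sample names and no negative values (`NA`
#' allowed, meaning "not measured").
#'
#' @param mat Matrix to check.
#' @return Invisibly, `mat`.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("expression data must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(mat))) stop("duplicated sample ids")
  if (any(mat < 0, na.rm = TRUE)) stop("negative expression values are not allowed")
  invisible(mat)
}

#' Map gene identifiers of an expression matrix
#'
#' Applies a source-to-target identifier mapping (e.g. Ensembl to Entrez).
#' Source genes that map to zero or to multiple targets are deleted. When
#' several source genes map to one target, the target's value in each sample
#' is the arithmetic mean of the source values; unmeasured (`NA`) sources are
#' ignored in the mean and the result is `NA` only when every contributing
#' source is unmeasured.
#'
#' @param mat Expression matrix (genes in rows).
#' @param mapping Data frame with columns `source` and `target` (one row per
#'   source/target link; a source listed with several distinct targets is
#'   treated as multi-mapped and dropped).
#' @return The mapped expression matrix, rows named by target ids.
#' @export
map_gene_ids <- function(mat, mapping) {
  validate_expression_matrix(mat)
  if (!all(c("source", "target") %in% names(mapping))) {
    stop("mapping must have columns 'source' and 'target'")
  }
  mapping <- unique(mapping[, c("source", "target")])
  mapping <- mapping[!is.na(mapping$source) & !is.na(mapping$target), ]
  n_targets <- table(mapping$source)
  unique_src <- names(n_targets)[n_targets == 1]
  mapping <- mapping[mapping$source %in% unique_src, ]
  keep <- rownames(mat) %in% mapping$source
  if (!any(keep)) stop("no gene maps to a unique target id; empty matrix after mapping")
  sub <- mat[keep, , drop = FALSE]
  tgt <- mapping$target[match(rownames(sub), mapping$source)]
  filled <- sub
  filled[is.na(sub)] <- 0
  sums <- rowsum(filled, tgt)
  counts <- rowsum((!is.na(sub)) * 1, tgt)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  out <- out[order(rownames(out)), , drop = FALSE]
  validate_expression_matrix(out)
  out
}

#' Read an identifier mapping table
#'
#' Two-column delimited file (`source`, `target`); a header row is optional
#' and detected by the literal column names.
#'
#' @param path Path to the file.
#' @param sep Delimiter; inferred from the extension when `NULL`.
#' @return Data frame with columns `source` and `target`.
#' @export
read_id_mapping <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% infer_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  header <- identical(tolower(trimws(first[1:2])), c("source", "target"))
  tab <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("mapping file must have two columns")
  out <- data.frame(source = tab[[1]], target = tab[[2]], stringsAsFactors = FALSE)
  out
}

#' Harmonize the gene universe across datasets
#'
#' Expands each matrix to the union of all gene ids; a gene absent from a
#' dataset behaves exactly like a gene that was not measured there (`NA`), so
#' downstream evaluability rules handle cross-dataset signature application
#' uniformly. Sample order is preserved.
#'
#' @param matrices List of expression matrices.
#' @return List of matrices, all with identical (sorted) gene rows.
#' @export
harmonize_gene_universe <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2) stop("need at least two matrices")
  lapply(matrices, validate_expression_matrix)
  universe <- sort(unique(unlist(lapply(matrices, rownames))))
  lapply(matrices, function(m) {
    out <- matrix(NA_real_, nrow = length(universe), ncol = ncol(m),
                  dimnames = list(universe, colnames(m)))
    out[rownames(m), ] <- m
    out
  })
}

#' Read a sample phenotype table
#'
#' CSV/TSV with columns `sample_id`, `group` (one of `normal`, `IBD`,
#' `cancer`) and optionally `stage` (`I`--`IV`, cancer samples only),
#' `relapse` (`relapse`/`non_relapse`) and `dataset`.
#'
#' @param path Path to the file.
#' @param sep Delimiter; inferred from the extension when `NULL`.
#' @return Data frame, one row per sample.
#' @export
read_phenotype_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% infer_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  validate_phenotype_table(tab)
}

#' Validate a phenotype table
#'
#' @param tab Data frame with at least `sample_id` and `group`.
#' @return The validated table (stage normalised to `NA` outside cancer).
#' @export
validate_phenotype_table <- function(tab) {
  if (!all(c("sample_id", "group") %in% names(tab))) {
    stop("phenotype table needs columns 'sample_id' and 'group'")
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicated sample ids in phenotype table")
  bad <- setdiff(unique(tab$group), c("normal", "IBD", "cancer"))
  if (length(bad) > 0) stop("unknown group labels: ", paste(bad, collapse = ", "))
  if (!is.null(tab$stage)) {
    misplaced <- !is.na(tab$stage) & tab$group != "cancer"
    if (any(misplaced)) stop("stage set for non-cancer samples: ",
                             paste(tab$sample_id[misplaced], collapse = ", "))
  }
  tab
}

#' Read a survival (follow-up) table
#'
#' CSV/TSV with columns `sample_id`, `time` (follow-up, months, positive) and
#' `event` (1 = relapse/event, 0 = censored); extra covariate columns are kept.
#'
#' @param path Path to the file.
#' @param sep Delimiter; inferred from the extension when `NULL`.
#' @return Data frame of survival records.
#' @export
read_survival_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% infer_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  validate_survival_records(tab)
}

validate_survival_records <- function(records) {
  if (!all(c("time", "event") %in% names(records))) {
    stop("survival records need columns 'time' and 'event'")
  }
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    stop("follow-up times must be positive")
  }
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 or 1")
  records
}
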