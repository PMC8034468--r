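#' Within-sample order relation of two expression values
#'
#' The relative expression ordering (REO) of a gene pair is the strict order
#' of the two genes' abundances within one sample. A pair is not evaluable
#' when both measurements are zero (nothing was detected for either gene) or
#' when either gene was not measured (`NA`); a pair with exactly one zero is
#' evaluable. Equal nonzero values are a `TIE`: evaluable, but matching
#' neither strict pattern.
#'
#' @param x_a,x_b Nonnegative abundances (vectors recycle as usual); `NA`
#'   means not measured.
#' @return Character vector with elements in `"GREATER"`, `"LESS"`, `"TIE"`,
#'   `"NOT_EVALUABLE"`, where `"GREATER"` means `x_a > x_b`.
#' @export
reo_sign <- function(x_a, x_b) {
  if (any(x_a < 0, na.rm = TRUE) || any(x_b < 0, na.rm = TRUE)) {
    stop("abundances must be nonnegative")
  }
  n <- max(length(x_a), length(x_b))
  x_a <- rep_len(x_a, n); x_b <- rep_len(x_b, n)
  out <- rep("NOT_EVALUABLE", n)
  ev <- !is.na(x_a) & !is.na(x_b) & !(x_a == 0 & x_b == 0)
  out[ev & x_a > x_b] <- "GREATER"
  out[ev & x_a < x_b] <- "LESS"
  out[ev & x_a == x_b] <- "TIE"
  out
}

# Vectorised pair statistics: for index pairs (ia, ib) into the rows of `mat`
# (already restricted to the sample subset), count evaluable samples and the
# strict GREATER / LESS outcomes. One pass per sample keeps memory at O(pairs).
pair_counts <- function(mat, ia, ib) {
  n_pairs <- length(ia)
  greater <- integer(n_pairs)
  less <- integer(n_pairs)
  n_eval <- integer(n_pairs)
  for (s in seq_len(ncol(mat))) {
    xa <- mat[ia, s]
    xb <- mat[ib, s]
    ev <- !is.na(xa) & !is.na(xb) & !(xa == 0 & xb == 0)
    gt <- ev & xa > xb
    lt <- ev & xa < xb
    greater <- greater + gt
    less <- less + lt
    n_eval <- n_eval + ev
  }
  list(greater = greater, less = less, n_eval = n_eval)
}

# Turn a candidate-pair data frame (or NULL = all pairs) into row indices.
candidate_indices <- function(genes, candidate_pairs, max_genes) {
  if (is.null(candidate_pairs)) {
    if (length(genes) > max_genes) {
      stop("full pair scan over ", length(genes), " genes exceeds max_genes = ",
           max_genes, "; pass candidate_pairs or raise max_genes")
    }
    if (length(genes) < 2) stop("need at least two genes")
    idx <- utils::combn(length(genes), 2)
    list(ia = idx[1, ], ib = idx[2, ])
  } else {
    ia <- match(candidate_pairs$gene_a, genes)
    ib <- match(candidate_pairs$gene_b, genes)
    keep <- !is.na(ia) & !is.na(ib) & ia != ib
    list(ia = ia[keep], ib = ib[keep])
  }
}

#' Frequency of the pattern gene_a > gene_b across samples
#'
#' @param mat Expression matrix.
#' @param gene_a,gene_b Gene identifiers (rows of `mat`).
#' @param samples Sample subset (default: all columns).
#' @return List with `freq` (fraction of evaluable samples showing
#'   `gene_a > gene_b`; ties count against the pattern), `n_evaluable`, and
#'   `evaluable` (`FALSE` when no sample is evaluable, in which case `freq`
#'   is `NA`).
#' @export
pair_pattern_frequency <- function(mat, gene_a, gene_b, samples = NULL) {
  validate_expression_matrix(mat)
  samples <- resolve_samples(mat, samples)
  if (length(samples) == 0) stop("empty sample subset")
  ia <- match(gene_a, rownames(mat)); ib <- match(gene_b, rownames(mat))
  if (is.na(ia) || is.na(ib)) stop("gene not present in matrix")
  cnt <- pair_counts(mat[, samples, drop = FALSE], ia, ib)
  if (cnt$n_eval == 0) {
    return(list(freq = NA_real_, n_evaluable = 0L, evaluable = FALSE))
  }
  list(freq = cnt$greater / cnt$n_eval, n_evaluable = cnt$n_eval, evaluable = TRUE)
}

#' Find stable gene pairs within one group
#'
#' A pair is stable when the same strict order holds in at least `threshold`
#' of the evaluable samples of the group. Each unordered pair is emitted at
#' most once, oriented so that `gene_a > gene_b` is the majority direction.
#'
#' @param mat Expression matrix.
#' @param samples Sample subset (default: all columns).
#' @param threshold Stability level in (0.5, 1]; the comparison is inclusive
#'   (a pair at exactly the threshold is kept).
#' @param candidate_pairs Optional data frame (`gene_a`, `gene_b`) restricting
#'   the scan; by default all gene pairs are scanned.
#' @param max_genes Guard for the quadratic full scan.
#' @return Data frame (`gene_a`, `gene_b`, `freq`, `n_evaluable`) with
#'   `gene_a > gene_b` the stable direction.
#' @export
find_stable_pairs <- function(mat, samples = NULL, threshold = 0.99,
                              candidate_pairs = NULL, max_genes = 3000) {
  validate_expression_matrix(mat)
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must be in (0.5, 1]: below a majority the orientation is ambiguous")
  }
  samples <- resolve_samples(mat, samples)
  sub <- mat[, samples, drop = FALSE]
  genes <- rownames(mat)
  ci <- candidate_indices(genes, candidate_pairs, max_genes)
  cnt <- pair_counts(sub, ci$ia, ci$ib)
  flip <- cnt$less > cnt$greater
  maj <- ifelse(flip, cnt$less, cnt$greater)
  freq <- ifelse(cnt$n_eval > 0, maj / cnt$n_eval, NA_real_)
  keep <- !is.na(freq) & freq >= threshold
  data.frame(
    gene_a = ifelse(flip, genes[ci$ib], genes[ci$ia])[keep],
    gene_b = ifelse(flip, genes[ci$ia], genes[ci$ib])[keep],
    freq = freq[keep],
    n_evaluable = cnt$n_eval[keep],
    stringsAsFactors = FALSE
  )
}

#' Find stable opposite gene pairs between two groups
#'
#' Pairs stable at `threshold` in both groups with opposite directions,
#' oriented to the reference group's direction (so `gene_a > gene_b` is the
#' reference -- e.g. cancer -- pattern). Exchanging the two groups maps each
#' emitted pair (a, b) to (b, a).
#'
#' @param mat_ref,mat_other Expression matrices for the reference and other
#'   group (may be the same matrix with different sample subsets).
#' @param samples_ref,samples_other Sample subsets.
#' @param threshold Stability level in (0.5, 1], inclusive.
#' @param candidate_pairs Optional pair universe; default scans all pairs of
#'   the shared gene set.
#' @param max_genes Guard for the full scan.
#' @return Data frame (`gene_a`, `gene_b`, `freq_ref`, `freq_other`,
#'   `n_eval_ref`, `n_eval_other`); `freq_other` is the frequency of the
#'   *reference* pattern in the other group (at most `1 - threshold`).
#' @export
find_stable_opposite_pairs <- function(mat_ref, mat_other,
                                       samples_ref = NULL, samples_other = NULL,
                                       threshold = 0.99, candidate_pairs = NULL,
                                       max_genes = 3000) {
  validate_expression_matrix(mat_ref)
  validate_expression_matrix(mat_other)
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  samples_ref <- resolve_samples(mat_ref, samples_ref)
  samples_other <- resolve_samples(mat_other, samples_other)
  if (length(samples_ref) == 0 || length(samples_other) == 0) {
    stop("both groups must be nonempty")
  }
  genes <- intersect(rownames(mat_ref), rownames(mat_other))
  if (length(genes) < 2) stop("fewer than two shared genes")
  ci <- candidate_indices(genes, candidate_pairs, max_genes)
  cr <- pair_counts(mat_ref[genes, samples_ref, drop = FALSE], ci$ia, ci$ib)
  co <- pair_counts(mat_other[genes, samples_other, drop = FALSE], ci$ia, ci$ib)
  freq_r_gt <- ifelse(cr$n_eval > 0, cr$greater / cr$n_eval, NA_real_)
  freq_r_lt <- ifelse(cr$n_eval > 0, cr$less / cr$n_eval, NA_real_)
  freq_o_gt <- ifelse(co$n_eval > 0, co$greater / co$n_eval, NA_real_)
  freq_o_lt <- ifelse(co$n_eval > 0, co$less / co$n_eval, NA_real_)
  # reference stable ">" while other stable "<", or the mirror image
  fwd <- !is.na(freq_r_gt) & !is.na(freq_o_lt) & freq_r_gt >= threshold & freq_o_lt >= threshold
  rev <- !is.na(freq_r_lt) & !is.na(freq_o_gt) & freq_r_lt >= threshold & freq_o_gt >= threshold
  out <- data.frame(
    gene_a = c(genes[ci$ia][fwd], genes[ci$ib][rev]),
    gene_b = c(genes[ci$ib][fwd], genes[ci$ia][rev]),
    freq_ref = c(freq_r_gt[fwd], freq_r_lt[rev]),
    freq_other = c(freq_o_gt[fwd], freq_o_lt[rev]),
    n_eval_ref = c(cr$n_eval[fwd], cr$n_eval[rev]),
    n_eval_other = c(co$n_eval[fwd], co$n_eval[rev]),
    stringsAsFactors = FALSE
  )
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Hypergeometric tail test for REO reversal between two groups
#'
#' Tests whether reversals of a pair's reference pattern (strict `LESS`
#' outcomes) concentrate in the other group. The two groups are pooled, the
#' total reversal count is taken as fixed, and the p-value is the one-sided
#' cumulative hypergeometric tail probability that at least the observed
#' number of reversals falls in the other group (the Fisher-style
#' margin-conditioned construction).
#'
#' @param n_ref,n_other Evaluable sample counts in the two groups.
#' @param k_ref_less,k_other_less Reversal (`LESS`) counts; must not exceed
#'   the corresponding evaluable counts. All arguments vectorise.
#' @return p-values in (0, 1]; all-zero counts give 1.
#' @export
opposite_pair_pvalue <- function(n_ref, k_ref_less, n_other, k_other_less) {
  n <- max(length(n_ref), length(k_ref_less), length(n_other), length(k_other_less))
  n_ref <- rep_len(n_ref, n); k_ref_less <- rep_len(k_ref_less, n)
  n_other <- rep_len(n_other, n); k_other_less <- rep_len(k_other_less, n)
  if (any(c(n_ref, k_ref_less, n_other, k_other_less) < 0)) stop("counts must be nonnegative")
  if (any(k_ref_less > n_ref) || any(k_other_less > n_other)) {
    stop("reversal counts cannot exceed evaluable counts")
  }
  total <- n_ref + n_other
  reversals <- k_ref_less + k_other_less
  p <- stats::phyper(k_other_less - 1, reversals, total - reversals, n_other,
                     lower.tail = FALSE)
  p[total == 0] <- 1
  pmin(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (thin wrapper over
#' [stats::p.adjust()] kept as the single adjustment route of the package).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Find significantly reversed (opposite) gene pairs between two groups
#'
#' Every candidate pair is oriented to the reference group's majority
#' direction, tested for reversal enrichment in the other group with
#' [opposite_pair_pvalue()], BH-adjusted across all tested pairs, and kept
#' when `q < fdr`.
#'
#' @inheritParams find_stable_opposite_pairs
#' @param fdr FDR level in (0, 1).
#' @return Data frame (`gene_a`, `gene_b`, `freq_ref`, `freq_other`,
#'   `n_eval_ref`, `n_eval_other`, `p_value`, `q_value`) oriented so that
#'   `gene_a > gene_b` is the reference pattern.
#' @export
find_significant_opposite_pairs <- function(mat_ref, mat_other,
                                            samples_ref = NULL, samples_other = NULL,
                                            fdr = 0.05, candidate_pairs = NULL,
                                            max_genes = 3000) {
  validate_expression_matrix(mat_ref)
  validate_expression_matrix(mat_other)
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  samples_ref <- resolve_samples(mat_ref, samples_ref)
  samples_other <- resolve_samples(mat_other, samples_other)
  genes <- intersect(rownames(mat_ref), rownames(mat_other))
  if (length(genes) < 2) stop("fewer than two shared genes")
  ci <- candidate_indices(genes, candidate_pairs, max_genes)
  if (length(ci$ia) == 0) return(empty_pairs(c("freq_ref", "freq_other",
                                               "n_eval_ref", "n_eval_other",
                                               "p_value", "q_value")))
  cr <- pair_counts(mat_ref[genes, samples_ref, drop = FALSE], ci$ia, ci$ib)
  co <- pair_counts(mat_other[genes, samples_other, drop = FALSE], ci$ia, ci$ib)
  # orient each pair to the reference majority (ties: lexicographic gene order)
  flip <- cr$less > cr$greater |
    (cr$less == cr$greater & genes[ci$ia] > genes[ci$ib])
  ga <- ifelse(flip, genes[ci$ib], genes[ci$ia])
  gb <- ifelse(flip, genes[ci$ia], genes[ci$ib])
  ref_gt <- ifelse(flip, cr$less, cr$greater)
  ref_lt <- ifelse(flip, cr$greater, cr$less)
  oth_gt <- ifelse(flip, co$less, co$greater)
  oth_lt <- ifelse(flip, co$greater, co$less)
  p <- opposite_pair_pvalue(cr$n_eval, ref_lt, co$n_eval, oth_lt)
  q <- bh_adjust(p)
  keep <- q < fdr
  out <- data.frame(
    gene_a = ga[keep], gene_b = gb[keep],
    freq_ref = ifelse(cr$n_eval > 0, ref_gt / cr$n_eval, NA_real_)[keep],
    freq_other = ifelse(co$n_eval > 0, oth_gt / co$n_eval, NA_real_)[keep],
    n_eval_ref = cr$n_eval[keep], n_eval_other = co$n_eval[keep],
    p_value = p[keep], q_value = q[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$p_value, out$gene_a, out$gene_b), , drop = FALSE]
}

#' Retention rate of a pair signature in a single sample
#'
#' Counts, over the signature's oriented pairs, how many are evaluable in the
#' sample (`m`: both genes measured, not both zero) and how many of those show
#' the asserted pattern `gene_a > gene_b` (`k`). The retention rate `k/m` is
#' the voting statistic of both signatures.
#'
#' @param x Named numeric vector: one sample's expression values, names are
#'   gene ids (`NA` = not measured; genes absent from `x` count as not
#'   measured).
#' @param pairs Data frame with columns `gene_a`, `gene_b` (the asserted
#'   pattern is `gene_a > gene_b`).
#' @return List with `k`, `m`, `ratio` (`NA` when `m == 0`) and `evaluable`.
#' @export
retention_rate <- function(x, pairs) {
  if (is.null(names(x))) stop("sample vector must be named by gene id")
  if (nrow(pairs) == 0) stop("signature must contain at least one pair")
  xa <- x[match(pairs$gene_a, names(x))]
  xb <- x[match(pairs$gene_b, names(x))]
  ev <- !is.na(xa) & !is.na(xb) & !(xa == 0 & xb == 0)
  m <- sum(ev)
  k <- sum(ev & xa > xb)
  list(k = k, m = m,
       ratio = if (m > 0) k / m else NA_real_,
       evaluable = m > 0)
}

#' Retention rates for every sample of a matrix
#'
#' @param mat Expression matrix.
#' @param pairs Oriented pair data frame as in [retention_rate()].
#' @param samples Sample subset (default: all).
#' @return Data frame (`sample_id`, `k`, `m`, `ratio`), one row per sample.
#' @export
retention_rates <- function(mat, pairs, samples = NULL) {
  validate_expression_matrix(mat)
  samples <- resolve_samples(mat, samples)
  ia <- match(pairs$gene_a, rownames(mat))
  ib <- match(pairs$gene_b, rownames(mat))
  res <- lapply(samples, function(s) {
    xa <- ifelse(is.na(ia), NA_real_, mat[ia, s])
    xb <- ifelse(is.na(ib), NA_real_, mat[ib, s])
    ev <- !is.na(xa) & !is.na(xb) & !(xa == 0 & xb == 0)
    m <- sum(ev)
    c(k = sum(ev & xa > xb), m = m)
  })
  res <- do.call(rbind, res)
  data.frame(sample_id = samples, k = res[, "k"], m = res[, "m"],
             ratio = ifelse(res[, "m"] > 0, res[, "k"] / res[, "m"], NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}
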