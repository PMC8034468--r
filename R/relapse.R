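#' DEG-anchored significant opposite pairs between stage I and stage IV
#'
#' Builds the relapse candidate universe: all gene pairs containing at least
#' one differentially expressed gene, tested for significant REO reversal
#' between the stage IV (reference; metastatic pattern) and stage I groups
#' with [find_significant_opposite_pairs()] at FDR < `fdr`. Pairs are oriented
#' to the stage IV pattern `gene_a > gene_b`.
#'
#' @param mat_iv,mat_i Expression matrices for stage IV and stage I.
#' @param degs Character vector of DEG gene ids (or a data frame with a
#'   `gene` column, e.g. from [rankcomp_degs()]).
#' @param samples_iv,samples_i Sample subsets.
#' @param fdr FDR level (default 0.01).
#' @return Data frame as from [find_significant_opposite_pairs()]; empty (with
#'   a warning) when nothing is significant.
#' @export
deg_anchored_opposite_pairs <- function(mat_iv, mat_i, degs,
                                        samples_iv = NULL, samples_i = NULL,
                                        fdr = 0.01) {
  if (is.data.frame(degs)) degs <- degs$gene
  degs <- unique(as.character(degs))
  if (length(degs) == 0) stop("DEG list is empty")
  genes <- intersect(rownames(mat_iv), rownames(mat_i))
  anchors <- intersect(degs, genes)
  if (length(anchors) == 0) stop("no DEG present in the expression matrices")
  others <- setdiff(genes, anchors)
  cand <- rbind(
    if (length(anchors) >= 2) {
      idx <- utils::combn(length(anchors), 2)
      data.frame(gene_a = anchors[idx[1, ]], gene_b = anchors[idx[2, ]],
                 stringsAsFactors = FALSE)
    },
    if (length(others) > 0) {
      expand.grid(gene_a = anchors, gene_b = others,
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }
  )
  out <- find_significant_opposite_pairs(mat_iv, mat_i, samples_iv, samples_i,
                                         fdr = fdr, candidate_pairs = cand,
                                         max_genes = Inf)
  if (nrow(out) == 0) warning("no significant DEG-anchored opposite pairs at FDR ", fdr)
  out
}

#' Filter pairs by FF/FFPE ordering concordance
#'
#' For each candidate gene pair, counts the paired fresh-frozen/FFPE samples
#' in which the pair shows the same strict ordering in both preservation
#' states (the pair must be evaluable -- not both-zero, both genes measured --
#' in both members, and ties match neither pattern). Pairs concordant in fewer
#' than `min_concordant` sample pairs are dropped: their ordering does not
#' survive degradation.
#'
#' @param pairs Candidate pair data frame.
#' @param ff_mat,ffpe_mat Expression matrices of the paired samples.
#' @param pairing Data frame with columns `ff` and `ffpe` giving the sample
#'   pairing (each FF sample mapped to exactly one FFPE sample).
#' @param min_concordant Minimum concordant sample pairs (default 10).
#' @return `pairs` with a `concordant_pairs` column, restricted to the kept
#'   rows.
#' @export
paired_concordance_filter <- function(pairs, ff_mat, ffpe_mat, pairing,
                                      min_concordant = 10) {
  if (nrow(pairing) == 0) stop("empty FF/FFPE pairing")
  if (!all(c("ff", "ffpe") %in% names(pairing))) {
    stop("pairing must have columns 'ff' and 'ffpe'")
  }
  if (anyDuplicated(pairing$ff) || anyDuplicated(pairing$ffpe)) {
    stop("pairing must map each sample exactly once")
  }
  resolve_samples(ff_mat, pairing$ff)
  resolve_samples(ffpe_mat, pairing$ffpe)
  if (nrow(pairs) == 0) return(cbind(pairs, concordant_pairs = integer(0)))
  ia_ff <- match(pairs$gene_a, rownames(ff_mat))
  ib_ff <- match(pairs$gene_b, rownames(ff_mat))
  ia_fp <- match(pairs$gene_a, rownames(ffpe_mat))
  ib_fp <- match(pairs$gene_b, rownames(ffpe_mat))
  conc <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairing))) {
    xf_a <- ff_mat[ia_ff, pairing$ff[i]]
    xf_b <- ff_mat[ib_ff, pairing$ff[i]]
    xp_a <- ffpe_mat[ia_fp, pairing$ffpe[i]]
    xp_b <- ffpe_mat[ib_fp, pairing$ffpe[i]]
    ev <- !is.na(xf_a) & !is.na(xf_b) & !(xf_a == 0 & xf_b == 0) &
          !is.na(xp_a) & !is.na(xp_b) & !(xp_a == 0 & xp_b == 0)
    same <- (xf_a > xf_b & xp_a > xp_b) | (xf_a < xf_b & xp_a < xp_b)
    conc <- conc + (ev & same)
  }
  out <- pairs[conc >= min_concordant, , drop = FALSE]
  out$concordant_pairs <- conc[conc >= min_concordant]
  row.names(out) <- NULL
  out
}

#' Coverage difference of the stage-IV pattern
#'
#' The coverage of a pair in a group is the frequency of the relapse pattern
#' `gene_a > gene_b` among evaluable samples (samples with both genes zero,
#' or either gene unmeasured, are not counted). The coverage difference
#' `c_ivi = coverage_iv - coverage_i` ranks candidates by how specifically
#' the pattern marks the metastatic group.
#'
#' @param pairs Oriented pair data frame.
#' @param mat_iv,mat_i Expression matrices.
#' @param samples_iv,samples_i Sample subsets.
#' @return `pairs` with columns `coverage_iv`, `coverage_i`, `c_ivi` appended
#'   (`NA` when a group has no evaluable sample for the pair).
#' @export
coverage_difference <- function(pairs, mat_iv, mat_i,
                                samples_iv = NULL, samples_i = NULL) {
  samples_iv <- resolve_samples(mat_iv, samples_iv)
  samples_i <- resolve_samples(mat_i, samples_i)
  cov_group <- function(mat, samples) {
    ia <- match(pairs$gene_a, rownames(mat))
    ib <- match(pairs$gene_b, rownames(mat))
    sub <- mat[, samples, drop = FALSE]
    ok <- !is.na(ia) & !is.na(ib)
    cnt <- pair_counts(sub, ifelse(ok, ia, 1L), ifelse(ok, ib, 1L))
    cov <- ifelse(ok & cnt$n_eval > 0, cnt$greater / cnt$n_eval, NA_real_)
    cov
  }
  pairs$coverage_iv <- cov_group(mat_iv, samples_iv)
  pairs$coverage_i <- cov_group(mat_i, samples_i)
  pairs$c_ivi <- pairs$coverage_iv - pairs$coverage_i
  pairs
}

#' Sort relapse candidates by coverage difference
#'
#' Descending signed `c_ivi`; ties broken by descending `coverage_iv`, then
#' lexicographic gene ids, so the partition into candidate signatures is
#' deterministic.
#'
#' @param pairs Pair data frame with `c_ivi` and `coverage_iv`.
#' @return Sorted data frame.
#' @export
sort_relapse_candidates <- function(pairs) {
  out <- pairs[order(-pairs$c_ivi, -pairs$coverage_iv, pairs$gene_a, pairs$gene_b), ,
               drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Partition ranked candidates into candidate-signature blocks
#'
#' The n-th block takes the next `base_size + step * (n - 1)` pairs of the
#' ranked list (3500, 4500, 5500, ... by default); the final block takes
#' whatever remains when the list is exhausted early.
#'
#' @param pairs Ranked pair data frame (see [sort_relapse_candidates()]).
#' @param base_size First block size.
#' @param step Increment per block.
#' @return List of data frames, one per block (empty list for empty input).
#' @export
partition_candidates <- function(pairs, base_size = 3500, step = 1000) {
  n <- nrow(pairs)
  blocks <- list()
  start <- 1L
  i <- 1L
  while (start <= n) {
    size <- min(base_size + step * (i - 1L), n - start + 1L)
    blk <- pairs[seq(start, start + size - 1L), , drop = FALSE]
    row.names(blk) <- NULL
    blocks[[i]] <- blk
    start <- start + size
    i <- i + 1L
  }
  blocks
}

#' Predict relapse risk for samples
#'
#' Voting rule of the relapse signature: a sample is `high_risk` when the
#' proportion of evaluable signature pairs showing the relapse pattern
#' `gene_a > gene_b` is strictly greater than the cut-off (note the strict
#' inequality, unlike the inclusive diagnosis vote), `low_risk` otherwise,
#' and `NOT_EVALUABLE` when no pair is evaluable.
#'
#' @param mat Expression matrix of samples to score.
#' @param pairs Oriented pair data frame (or a `reo_relapse` object).
#' @param cutoff Vote cut-off (default 0.49).
#' @param samples Sample subset.
#' @return Data frame (`sample_id`, `k`, `m`, `ratio`, `label`).
#' @export
predict_relapse <- function(mat, pairs, cutoff = 0.49, samples = NULL) {
  if (inherits(pairs, "reo_relapse")) {
    cutoff <- if (missing(cutoff)) pairs$vote_cutoff else cutoff
    pairs <- pairs$pairs
  }
  if (nrow(pairs) == 0) stop("signature must contain at least one pair")
  res <- retention_rates(mat, pairs, samples)
  res$label <- ifelse(res$m == 0, "NOT_EVALUABLE",
                      ifelse(res$ratio > cutoff, "high_risk", "low_risk"))
  res
}

#' Select the relapse signature from candidate blocks
#'
#' Evaluates every (block, cut-off) combination on the training groups: the
#' stage I accuracy is the fraction of stage I samples voted `low_risk`, the
#' stage IV accuracy the fraction of stage IV samples voted `high_risk`
#' (micro-metastasis reading: stage IV carries the relapse pattern, stage I
#' does not). The cut-off maximising the mean stage IV accuracy is chosen
#' (ties: the smaller cut-off); among blocks whose two accuracies both exceed
#' `min_accuracy` at that cut-off, the block with the most pairs wins --
#' more pairs, more robustness against degraded samples. If no block passes,
#' the block with the best worst-group accuracy is returned with a warning.
#'
#' @param blocks List of candidate pair blocks ([partition_candidates()]).
#' @param mat_iv,mat_i Training expression matrices.
#' @param samples_iv,samples_i Sample subsets.
#' @param cutoffs Candidate vote cut-offs (default 49%, 50%, 51%).
#' @param min_accuracy Acceptance level for both training accuracies.
#' @return An object of class `reo_relapse`: `pairs` (the chosen block),
#'   `block_index`, `vote_cutoff`, `grid` (the full selection grid with
#'   per-block/cut-off accuracies) and training sizes.
#' @export
select_relapse_signature <- function(blocks, mat_iv, mat_i,
                                     samples_iv = NULL, samples_i = NULL,
                                     cutoffs = c(0.49, 0.50, 0.51),
                                     min_accuracy = 0.80) {
  if (length(blocks) == 0) stop("no candidate blocks")
  samples_iv <- resolve_samples(mat_iv, samples_iv)
  samples_i <- resolve_samples(mat_i, samples_i)
  grid <- do.call(rbind, lapply(seq_along(blocks), function(b) {
    ratio_iv <- retention_rates(mat_iv, blocks[[b]], samples_iv)$ratio
    ratio_i <- retention_rates(mat_i, blocks[[b]], samples_i)$ratio
    do.call(rbind, lapply(cutoffs, function(ct) {
      data.frame(block = b, n_pairs = nrow(blocks[[b]]), cutoff = ct,
                 acc_iv = mean(!is.na(ratio_iv) & ratio_iv > ct),
                 acc_i = mean(!is.na(ratio_i) & ratio_i <= ct))
    }))
  }))
  mean_iv <- tapply(grid$acc_iv, grid$cutoff, mean)
  best_cutoff <- as.numeric(names(mean_iv))[which.max(mean_iv)]
  at_best <- grid[grid$cutoff == best_cutoff, , drop = FALSE]
  passing <- at_best[at_best$acc_iv > min_accuracy & at_best$acc_i > min_accuracy, ,
                     drop = FALSE]
  if (nrow(passing) > 0) {
    chosen <- passing$block[order(-passing$n_pairs, -passing$block)][1]
  } else {
    warning("no candidate block reaches ", 100 * min_accuracy,
            "% in both groups; returning the best by worst-group accuracy")
    worst <- pmin(at_best$acc_iv, at_best$acc_i)
    chosen <- at_best$block[which.max(worst)]
  }
  structure(list(
    pairs = blocks[[chosen]],
    block_index = chosen,
    vote_cutoff = best_cutoff,
    grid = grid,
    n_iv = length(samples_iv),
    n_i = length(samples_i)
  ), class = "reo_relapse")
}

#' @export
print.reo_relapse <- function(x, ...) {
  cat("REO relapse-risk signature\n")
  cat(sprintf("  %d gene pairs (candidate block %d)\n", nrow(x$pairs), x$block_index))
  cat(sprintf("  voting rule: high risk iff retention rate > %.0f%%\n",
              100 * x$vote_cutoff))
  at <- x$grid[x$grid$block == x$block_index & x$grid$cutoff == x$vote_cutoff, ]
  cat(sprintf("  training accuracy: stage I %.1f%%, stage IV %.1f%% (n = %d / %d)\n",
              100 * at$acc_i, 100 * at$acc_iv, x$n_i, x$n_iv))
  invisible(x)
}

#' @export
summary.reo_relapse <- function(object, ...) {
  print(object)
  cat("\nSelection grid:\n")
  print(object$grid, row.names = FALSE)
  invisible(object)
}

#' @export
coef.reo_relapse <- function(object, ...) object$pairs

#' @export
predict.reo_relapse <- function(object, newdata, cutoff = NULL, ...) {
  predict_relapse(newdata, object$pairs, cutoff %||% object$vote_cutoff)
}
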