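#' Rank-transform one sample's expression profile
#'
#' Genes are ranked in ascending order of abundance (rank 1 = lowest) over the
#' measured genes only; ties receive mid-ranks. Unmeasured (`NA`) genes keep
#' `NA` and are excluded from the ranking, so the measured ranks always sum to
#' n(n+1)/2.
#'
#' @param x Named numeric vector of abundances.
#' @return Named numeric vector of ranks (`NA` where unmeasured).
#' @export
rank_transform <- function(x) {
  measured <- !is.na(x)
  if (sum(measured) < 2) stop("need at least two measured genes to rank")
  out <- rep(NA_real_, length(x))
  names(out) <- names(x)
  out[measured] <- rank(x[measured], ties.method = "average")
  out
}

#' Signed rank difference of a gene pair in one sample
#'
#' @param ranks Rank vector from [rank_transform()].
#' @param gene_a,gene_b Gene identifiers.
#' @return `rank(gene_a) - rank(gene_b)`, or `NA` when either gene is
#'   unranked.
#' @export
rank_difference <- function(ranks, gene_a, gene_b) {
  ra <- ranks[match(gene_a, names(ranks))]
  rb <- ranks[match(gene_b, names(ranks))]
  unname(ra - rb)
}

#' Score oriented pairs by average rank difference
#'
#' For each pair the signed rank difference (rank of `gene_a` minus rank of
#' `gene_b`, ranks recomputed within each sample) is averaged over the samples
#' of the cancer group and of the normal group separately, using only samples
#' where the pair is evaluable (both genes measured, not both zero). The score
#' is the geometric mean of the two absolute group means,
#' `avg_rd = sqrt(|mean_rd_cancer| * |mean_rd_normal|)`; it is invariant to
#' swapping the two genes and orders pairs identically to the plain product of
#' the absolute means.
#'
#' @param pairs Data frame (`gene_a`, `gene_b`), oriented to the cancer
#'   pattern.
#' @param mat_cancer,mat_normal Expression matrices.
#' @param samples_cancer,samples_normal Sample subsets.
#' @return `pairs` with columns `mean_rd_cancer`, `mean_rd_normal`, `avg_rd`
#'   appended. Pairs with no evaluable sample in either group are dropped with
#'   a warning (an error if every pair is dropped).
#' @export
avg_rank_difference <- function(pairs, mat_cancer, mat_normal,
                                samples_cancer = NULL, samples_normal = NULL) {
  if (nrow(pairs) == 0) stop("no pairs to score")
  mean_rd <- function(mat, samples) {
    samples <- resolve_samples(mat, samples)
    sub <- mat[, samples, drop = FALSE]
    ranks <- apply(sub, 2, rank_transform)
    ia <- match(pairs$gene_a, rownames(mat))
    ib <- match(pairs$gene_b, rownames(mat))
    rd_sum <- numeric(nrow(pairs))
    rd_n <- integer(nrow(pairs))
    for (s in seq_len(ncol(sub))) {
      xa <- sub[ia, s]; xb <- sub[ib, s]
      ev <- !is.na(xa) & !is.na(xb) & !(xa == 0 & xb == 0)
      rd <- ranks[ia, s] - ranks[ib, s]
      rd_sum <- rd_sum + ifelse(ev, rd, 0)
      rd_n <- rd_n + ev
    }
    ifelse(rd_n > 0, rd_sum / rd_n, NA_real_)
  }
  mc <- mean_rd(mat_cancer, samples_cancer)
  mn <- mean_rd(mat_normal, samples_normal)
  bad <- is.na(mc) | is.na(mn)
  if (all(bad)) stop("no pair is evaluable in both groups")
  if (any(bad)) {
    warning(sum(bad), " pair(s) with no evaluable sample in a group dropped")
  }
  out <- pairs[!bad, , drop = FALSE]
  out$mean_rd_cancer <- mc[!bad]
  out$mean_rd_normal <- mn[!bad]
  out$avg_rd <- sqrt(abs(out$mean_rd_cancer) * abs(out$mean_rd_normal))
  row.names(out) <- NULL
  out
}

#' Remove gene-sharing redundancy from scored pairs
#'
#' Greedy scan in descending `avg_rd` (ties broken by lexicographic
#' `gene_a`, then `gene_b`): a pair is kept iff neither of its genes appears
#' in an already-kept pair, so every gene occurs at most once in the result.
#'
#' @param scored Data frame with `gene_a`, `gene_b`, `avg_rd`.
#' @return The kept rows, in descending-score order.
#' @export
remove_redundant_pairs <- function(scored) {
  if (nrow(scored) == 0) return(scored)
  ord <- order(-scored$avg_rd, scored$gene_a, scored$gene_b)
  scored <- scored[ord, , drop = FALSE]
  seen <- new.env(parent = emptyenv())
  keep <- logical(nrow(scored))
  for (i in seq_len(nrow(scored))) {
    a <- scored$gene_a[i]; b <- scored$gene_b[i]
    if (is.null(seen[[a]]) && is.null(seen[[b]])) {
      keep[i] <- TRUE
      seen[[a]] <- TRUE
      seen[[b]] <- TRUE
    }
  }
  out <- scored[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Build an early-diagnosis REO signature
#'
#' Fits the many-pair diagnosis classifier: stable opposite gene pairs between
#' the cancer and normal training groups are scored by average rank difference
#' ([avg_rank_difference()]), de-duplicated so that no gene appears twice
#' ([remove_redundant_pairs()]), and all surviving pairs -- oriented to the
#' cancer pattern `gene_a > gene_b` -- form the signature. New samples are
#' labelled by the retention-rate vote ([predict.reo_diagnosis()]).
#'
#' @param mat_cancer,mat_normal Training expression matrices.
#' @param samples_cancer,samples_normal Sample subsets (default: all columns).
#' @param stable_threshold Stability level for opposite-pair discovery.
#' @param vote_cutoff Retention-rate cut-off of the voting rule; a sample with
#'   retention at or above the cut-off is called cancer.
#' @param candidate_pairs Optional pair universe.
#' @param max_genes Guard for the quadratic scan.
#' @return An object of class `reo_diagnosis` with elements `pairs` (scored,
#'   de-duplicated signature pairs), `vote_cutoff`, `stable_threshold`,
#'   `n_candidates` (stable opposite pairs before redundancy removal) and the
#'   training group sizes.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_genes = 60, n_diag_pairs = 5,
#'                                      n_relapse_pairs = 0, seed = 1))
#' ph <- cohort$phenotype
#' sig <- build_diagnosis_signature(
#'   cohort$expression, cohort$expression,
#'   samples_cancer = ph$sample_id[ph$group == "cancer" & ph$stage == "I"],
#'   samples_normal = ph$sample_id[ph$group == "normal"],
#'   stable_threshold = 0.95)
#' print(sig)
#' @export
build_diagnosis_signature <- function(mat_cancer, mat_normal,
                                      samples_cancer = NULL, samples_normal = NULL,
                                      stable_threshold = 0.99, vote_cutoff = 0.60,
                                      candidate_pairs = NULL, max_genes = 3000) {
  if (vote_cutoff <= 0 || vote_cutoff >= 1) stop("vote_cutoff must be in (0, 1)")
  samples_cancer <- resolve_samples(mat_cancer, samples_cancer)
  samples_normal <- resolve_samples(mat_normal, samples_normal)
  stable <- find_stable_opposite_pairs(mat_cancer, mat_normal,
                                       samples_cancer, samples_normal,
                                       threshold = stable_threshold,
                                       candidate_pairs = candidate_pairs,
                                       max_genes = max_genes)
  if (nrow(stable) == 0) stop("no stable opposite pairs at threshold ", stable_threshold)
  scored <- avg_rank_difference(stable, mat_cancer, mat_normal,
                                samples_cancer, samples_normal)
  pairs <- remove_redundant_pairs(scored)
  if (nrow(pairs) == 0) stop("no pairs survive redundancy removal")
  structure(list(
    pairs = pairs,
    vote_cutoff = vote_cutoff,
    stable_threshold = stable_threshold,
    n_candidates = nrow(stable),
    n_cancer = length(samples_cancer),
    n_normal = length(samples_normal)
  ), class = "reo_diagnosis")
}

#' @export
print.reo_diagnosis <- function(x, ...) {
  cat("REO early-diagnosis signature\n")
  cat(sprintf("  %d gene pairs (from %d stable opposite pairs at %.0f%% stability)\n",
              nrow(x$pairs), x$n_candidates, 100 * x$stable_threshold))
  cat(sprintf("  voting rule: cancer iff retention rate >= %.0f%%\n", 100 * x$vote_cutoff))
  cat(sprintf("  trained on %d cancer / %d normal samples\n", x$n_cancer, x$n_normal))
  invisible(x)
}

#' @export
summary.reo_diagnosis <- function(object, ...) {
  cat("REO early-diagnosis signature\n\n")
  print(object)
  cat("\nTop pairs by avg_rd:\n")
  print(utils::head(object$pairs[, c("gene_a", "gene_b", "avg_rd")], 10),
        row.names = FALSE)
  invisible(object)
}

#' @export
coef.reo_diagnosis <- function(object, ...) object$pairs

#' Classify samples with a diagnosis signature
#'
#' Applies the retention-rate voting rule: a sample is labelled `"CRC"` when
#' the fraction of evaluable signature pairs showing the cancer pattern is at
#' least the cut-off (inclusive), `"non_cancer"` otherwise, and
#' `"NOT_EVALUABLE"` when no signature pair is evaluable.
#'
#' @param object A `reo_diagnosis` signature.
#' @param newdata Expression matrix of samples to classify.
#' @param cutoff Override of the stored vote cut-off.
#' @param ... Unused.
#' @return Data frame (`sample_id`, `k`, `m`, `ratio`, `label`).
#' @export
predict.reo_diagnosis <- function(object, newdata, cutoff = NULL, ...) {
  cutoff <- cutoff %||% object$vote_cutoff
  res <- retention_rates(newdata, object$pairs)
  res$label <- ifelse(res$m == 0, "NOT_EVALUABLE",
                      ifelse(res$ratio >= cutoff, "CRC", "non_cancer"))
  res
}

#' Classify a single sample
#'
#' Convenience wrapper around [predict.reo_diagnosis()] for one named
#' expression vector.
#'
#' @param x Named numeric vector (one sample).
#' @param signature A `reo_diagnosis` object.
#' @param cutoff Optional cut-off override.
#' @return List with `label` and the retention result (`k`, `m`, `ratio`).
#' @export
classify_sample <- function(x, signature, cutoff = NULL) {
  stopifnot(inherits(signature, "reo_diagnosis"))
  cutoff <- cutoff %||% signature$vote_cutoff
  ret <- retention_rate(x, signature$pairs)
  label <- if (!ret$evaluable) "NOT_EVALUABLE"
  else if (ret$ratio >= cutoff) "CRC" else "non_cancer"
  list(label = label, retention = ret)
}

#' Plot retention-rate distributions of classified samples
#'
#' Histogram of per-sample retention rates with the voting cut-off marked;
#' useful for seeing how far the cancer and non-cancer populations sit from
#' the decision boundary.
#'
#' @param x A `reo_diagnosis` signature.
#' @param newdata Expression matrix to classify and plot.
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, the prediction data frame.
#' @export
plot.reo_diagnosis <- function(x, newdata, ...) {
  pred <- predict(x, newdata)
  graphics::hist(pred$ratio, breaks = 20, xlim = c(0, 1),
                 main = "Signature retention rates",
                 xlab = "retention rate (k/m)", ...)
  graphics::abline(v = x$vote_cutoff, lty = 2)
  invisible(pred)
}

#' Pooled percentage accuracy
#'
#' Sums correct and total counts before dividing, as used for the pooled rows
#' of a multi-dataset performance table.
#'
#' @param correct Vector of per-dataset correct counts.
#' @param total Vector of per-dataset totals.
#' @return `100 * sum(correct) / sum(total)`.
#' @export
pool_accuracy <- function(correct, total) {
  if (length(correct) != length(total)) stop("count vectors must have equal length")
  if (any(correct > total)) stop("correct counts cannot exceed totals")
  100 * sum(correct) / sum(total)
}

#' Per-group and pooled classification accuracy
#'
#' Classifies every phenotyped sample and tabulates accuracy per
#' (dataset x group): cancer samples count as correct when labelled `"CRC"`,
#' normal and IBD samples when labelled `"non_cancer"` (a `"NOT_EVALUABLE"`
#' call is never correct). Pooled rows sum counts over datasets before
#' dividing, separately for the cancer and the non-cancer (normal + IBD)
#' samples.
#'
#' @param mat Expression matrix.
#' @param phenotypes Phenotype table (`sample_id`, `group`, optional
#'   `dataset`).
#' @param signature A `reo_diagnosis` object.
#' @param cutoff Optional vote cut-off override.
#' @return Data frame (`dataset`, `group`, `n`, `n_correct`, `accuracy_pct`)
#'   with pooled rows `dataset = "pooled"`, `group = "cancer"` /
#'   `"non_cancer"` appended. Samples without a phenotype row are excluded
#'   with a warning.
#' @export
evaluate_accuracy <- function(mat, phenotypes, signature, cutoff = NULL) {
  phenotypes <- validate_phenotype_table(phenotypes)
  pred <- predict(signature, mat, cutoff = cutoff)
  unphenotyped <- setdiff(pred$sample_id, phenotypes$sample_id)
  if (length(unphenotyped) > 0) {
    warning(length(unphenotyped), " sample(s) without phenotype excluded")
  }
  merged <- merge(pred, phenotypes, by = "sample_id")
  merged$dataset <- if (is.null(merged$dataset)) "all" else merged$dataset
  expected <- ifelse(merged$group == "cancer", "CRC", "non_cancer")
  merged$correct <- merged$label == expected
  agg <- stats::aggregate(correct ~ dataset + group, data = merged,
                          FUN = function(z) c(n = length(z), ok = sum(z)))
  out <- data.frame(dataset = agg$dataset, group = agg$group,
                    n = agg$correct[, "n"], n_correct = agg$correct[, "ok"],
                    stringsAsFactors = FALSE)
  pooled <- function(groups, label) {
    rows <- out[out$group %in% groups, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    data.frame(dataset = "pooled", group = label,
               n = sum(rows$n), n_correct = sum(rows$n_correct),
               stringsAsFactors = FALSE)
  }
  out <- rbind(out, pooled("cancer", "cancer"), pooled(c("normal", "IBD"), "non_cancer"))
  out$accuracy_pct <- pool_accuracy_rows(out)
  out
}

pool_accuracy_rows <- function(tab) 100 * tab$n_correct / tab$n
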