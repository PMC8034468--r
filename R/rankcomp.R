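#' Significantly stable gene pairs by the binomial test
#'
#' For each pair the majority direction over evaluable samples is tested
#' against a fair-coin null with the one-sided exact binomial tail
#' `P(X >= k_majority | n_evaluable, p = 0.5)`, BH-adjusted across all tested
#' pairs; pairs with `q < fdr` are kept, oriented to the majority direction.
#' This is the stable-pair step of the rank-comparison DEG caller.
#'
#' @inheritParams find_stable_pairs
#' @param fdr FDR level (default 0.20).
#' @return Data frame (`gene_a`, `gene_b`, `n_evaluable`, `n_majority`,
#'   `p_value`, `q_value`) with `gene_a > gene_b` the majority direction.
#' @export
stable_pairs_binomial <- function(mat, samples = NULL, fdr = 0.20,
                                  candidate_pairs = NULL, max_genes = 3000) {
  validate_expression_matrix(mat)
  samples <- resolve_samples(mat, samples)
  if (length(samples) < 1) stop("need at least one sample")
  genes <- rownames(mat)
  ci <- candidate_indices(genes, candidate_pairs, max_genes)
  cnt <- pair_counts(mat[, samples, drop = FALSE], ci$ia, ci$ib)
  flip <- cnt$less > cnt$greater |
    (cnt$less == cnt$greater & genes[ci$ia] > genes[ci$ib])
  k_maj <- pmax(cnt$greater, cnt$less)
  p <- stats::pbinom(k_maj - 1, cnt$n_eval, 0.5, lower.tail = FALSE)
  p[cnt$n_eval == 0] <- 1
  q <- bh_adjust(p)
  keep <- q < fdr
  data.frame(
    gene_a = ifelse(flip, genes[ci$ib], genes[ci$ia])[keep],
    gene_b = ifelse(flip, genes[ci$ia], genes[ci$ib])[keep],
    n_evaluable = cnt$n_eval[keep],
    n_majority = k_maj[keep],
    p_value = p[keep],
    q_value = q[keep],
    stringsAsFactors = FALSE
  )
}

#' Rank-comparison differential expression between two groups
#'
#' Single-pass rank-comparison caller: (1) significantly stable pairs are
#' found in each group separately ([stable_pairs_binomial()], FDR <
#' `stable_fdr`); (2) the pair universe is restricted to pairs stable in both
#' groups; (3) for each gene `g` a 2x2 table of its stable partners --
#' partners ranked below vs above `g`, in group A vs group B -- is tested with
#' the two-sided Fisher exact test and BH-adjusted. Genes with `q < deg_fdr`
#' are reported as differentially expressed; the direction is `"up"` when the
#' fraction of partners below `g` rises in group B.
#'
#' Swapping the two groups flips every direction and leaves p-values
#' unchanged.
#'
#' @param mat_a,mat_b Expression matrices of the two groups.
#' @param samples_a,samples_b Sample subsets.
#' @param stable_fdr FDR for the within-group stable-pair step.
#' @param deg_fdr FDR for the gene-level Fisher step.
#' @param candidate_pairs,max_genes Passed to the stable-pair scans.
#' @param all Return every tested gene (with a logical `deg` column) instead
#'   of only the significant ones.
#' @return Data frame (`gene`, `direction`, `p_value`, `q_value`, `a_below`,
#'   `a_above`, `b_below`, `b_above`). Genes without stable partners are
#'   skipped.
#' @export
rankcomp_degs <- function(mat_a, mat_b, samples_a = NULL, samples_b = NULL,
                          stable_fdr = 0.20, deg_fdr = 0.05,
                          candidate_pairs = NULL, max_genes = 3000,
                          all = FALSE) {
  stable_a <- stable_pairs_binomial(mat_a, samples_a, fdr = stable_fdr,
                                    candidate_pairs = candidate_pairs,
                                    max_genes = max_genes)
  stable_b <- stable_pairs_binomial(mat_b, samples_b, fdr = stable_fdr,
                                    candidate_pairs = candidate_pairs,
                                    max_genes = max_genes)
  if (nrow(stable_a) == 0 || nrow(stable_b) == 0) {
    stop("no stable pairs in one of the groups")
  }
  key_a <- pair_key(stable_a$gene_a, stable_a$gene_b)
  key_b <- pair_key(stable_b$gene_a, stable_b$gene_b)
  common <- intersect(key_a, key_b)
  if (length(common) == 0) stop("stable-pair lists do not overlap")
  ua <- stable_a[match(common, key_a), c("gene_a", "gene_b")]
  ub <- stable_b[match(common, key_b), c("gene_a", "gene_b")]
  genes <- sort(unique(c(ua$gene_a, ua$gene_b)))
  # winner counts: in each group, how many stable partners sit below / above g
  below_a <- table(factor(ua$gene_a, levels = genes))
  above_a <- table(factor(ua$gene_b, levels = genes))
  below_b <- table(factor(ub$gene_a, levels = genes))
  above_b <- table(factor(ub$gene_b, levels = genes))
  tab <- data.frame(gene = genes,
                    a_below = as.integer(below_a), a_above = as.integer(above_a),
                    b_below = as.integer(below_b), b_above = as.integer(above_b),
                    stringsAsFactors = FALSE)
  tab <- tab[tab$a_below + tab$a_above > 0, , drop = FALSE]
  tab$p_value <- vapply(seq_len(nrow(tab)), function(i) {
    m <- matrix(c(tab$a_below[i], tab$a_above[i], tab$b_below[i], tab$b_above[i]),
                nrow = 2, byrow = TRUE)
    min(stats::fisher.test(m)$p.value, 1)  # guard the > 1 float artefact
  }, numeric(1))
  tab$q_value <- bh_adjust(tab$p_value)
  frac_a <- tab$a_below / (tab$a_below + tab$a_above)
  frac_b <- tab$b_below / (tab$b_below + tab$b_above)
  tab$direction <- ifelse(frac_b >= frac_a, "up", "down")
  tab$deg <- tab$q_value < deg_fdr
  tab <- tab[order(tab$p_value, tab$gene),
             c("gene", "direction", "p_value", "q_value",
               "a_below", "a_above", "b_below", "b_above", "deg")]
  row.names(tab) <- NULL
  if (all) tab else tab[tab$deg, setdiff(names(tab), "deg"), drop = FALSE]
}
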