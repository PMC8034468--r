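# shared small cohort with planted relapse structure
relapse_cohort <- function(seed, ...) {
  simulate_cohort(sim_config(n_genes = 300, n_diag_pairs = 20,
                             n_relapse_pairs = 30, seed = seed, ...))
}

stage_samples <- function(co, st) {
  ph <- co$phenotype
  ph$sample_id[ph$group == "cancer" & !is.na(ph$stage) & ph$stage == st]
}

test_that("candidate pairs must contain a differential gene", {
  co <- relapse_cohort(41)
  si <- stage_samples(co, "I"); siv <- stage_samples(co, "IV")
  degs <- co$truth$deg_genes$gene
  cand <- deg_anchored_opposite_pairs(co$expression, co$expression, degs,
                                      samples_iv = siv, samples_i = si, fdr = 0.01)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$gene_a %in% degs | cand$gene_b %in% degs))
  # the planted relapse pairs themselves are found, oriented to stage IV
  truth <- co$truth$relapse_pairs
  expect_gte(mean(tkey(truth$gene_a, truth$gene_b) %in% tkey(cand$gene_a, cand$gene_b)),
             0.9)
  # loosening the FDR can only add pairs
  loose <- deg_anchored_opposite_pairs(co$expression, co$expression, degs,
                                       samples_iv = siv, samples_i = si, fdr = 0.2)
  expect_true(all(tkey(cand$gene_a, cand$gene_b) %in% tkey(loose$gene_a, loose$gene_b)))
  expect_error(deg_anchored_opposite_pairs(co$expression, co$expression, character(0)),
               "empty")
})

test_that("the FF/FFPE filter counts strict within-pair ordering concordance", {
  genes <- c("a", "b")
  ff <- make_mat(rbind(rep(5, 13), rep(2, 13)), genes = genes,
                 samples = sprintf("ff%02d", 1:13))
  ffpe <- ff * 0.9
  colnames(ffpe) <- sprintf("fp%02d", 1:13)
  pairing <- data.frame(ff = colnames(ff), ffpe = colnames(ffpe))
  pairs <- data.frame(gene_a = "a", gene_b = "b")

  expect_identical(paired_concordance_filter(pairs, ff, ffpe, pairing)$concordant_pairs, 13L)

  # concordant in exactly 10 of 13: kept; in 9: dropped
  ffpe10 <- ffpe; ffpe10["a", 1:3] <- 0.1       # reversed in 3
  expect_identical(nrow(paired_concordance_filter(pairs, ff, ffpe10, pairing)), 1L)
  ffpe9 <- ffpe; ffpe9["a", 1:4] <- 0.1
  expect_identical(nrow(paired_concordance_filter(pairs, ff, ffpe9, pairing)), 0L)

  # a both-zero member is not evaluable, hence not concordant
  ffpe_z <- ffpe; ffpe_z[, 1:4] <- 0
  expect_identical(paired_concordance_filter(pairs, ff, ffpe_z, pairing,
                                             min_concordant = 1)$concordant_pairs, 9L)
  expect_error(paired_concordance_filter(pairs, ff, ffpe, pairing[0, ]), "empty")
})

test_that("coverage differences follow the stage-IV pattern frequency arithmetic", {
  mk <- function(n_pattern, n_total) {
    make_mat(rbind(c(rep(3, n_pattern), rep(1, n_total - n_pattern)),
                   rep(2, n_total)), genes = c("a", "b"),
             samples = sprintf("x%02d", seq_len(n_total)))
  }
  pairs <- data.frame(gene_a = "a", gene_b = "b")
  out <- coverage_difference(pairs, mk(9, 10), mk(2, 10))
  expect_equal(out$coverage_iv, 0.9)
  expect_equal(out$coverage_i, 0.2)
  expect_equal(out$c_ivi, 0.7)
  # identical groups: no difference
  same <- coverage_difference(pairs, mk(5, 10), mk(5, 10))
  expect_equal(same$c_ivi, 0)
  # flipping the orientation negates the difference
  flipped <- coverage_difference(data.frame(gene_a = "b", gene_b = "a"),
                                 mk(9, 10), mk(2, 10))
  expect_equal(flipped$c_ivi, -out$c_ivi)
  # both-zero samples leave the denominator
  m_iv <- mk(9, 10); m_iv[, 10] <- 0
  out2 <- coverage_difference(pairs, m_iv, mk(2, 10))
  expect_equal(out2$coverage_iv, 9 / 9)
})

test_that("candidate partitioning reproduces the arithmetic block layout", {
  fake <- function(n) data.frame(gene_a = sprintf("a%05d", seq_len(n)),
                                 gene_b = sprintf("b%05d", seq_len(n)))
  sizes <- function(blocks) vapply(blocks, nrow, 0L)
  expect_identical(sizes(partition_candidates(fake(35349))),
                   c(3500L, 4500L, 5500L, 6500L, 7500L, 7849L))
  expect_identical(sizes(partition_candidates(fake(8000))), c(3500L, 4500L))
  expect_identical(sizes(partition_candidates(fake(3000))), 3000L)
  expect_identical(partition_candidates(fake(0)), list())
  # blocks are disjoint, ordered, and recompose the input
  blocks <- partition_candidates(fake(9000))
  expect_identical(do.call(rbind, blocks)$gene_a, fake(9000)$gene_a)
})

test_that("the relapse vote is strictly greater than the cut-off", {
  pairs <- data.frame(gene_a = sprintf("a%d", 1:100), gene_b = sprintf("b%d", 1:100))
  mk <- function(n_match) {
    x <- stats::setNames(rep(1, 200), c(pairs$gene_a, pairs$gene_b))
    x[pairs$gene_a] <- 0.5
    if (n_match > 0) x[pairs$gene_a[seq_len(n_match)]] <- 2
    matrix(x, ncol = 1, dimnames = list(names(x), "s1"))
  }
  expect_identical(predict_relapse(mk(50), pairs, cutoff = 0.49)$label, "high_risk")
  expect_identical(predict_relapse(mk(49), pairs, cutoff = 0.49)$label, "low_risk")
  expect_identical(predict_relapse(mk(0), pairs, cutoff = 0.49)$label, "low_risk")
  allna <- matrix(NA_real_, nrow = 200, ncol = 1,
                  dimnames = list(c(pairs$gene_a, pairs$gene_b), "s1"))
  expect_identical(predict_relapse(allna, pairs, cutoff = 0.49)$label, "NOT_EVALUABLE")
})

test_that("signature selection prefers the largest block passing both accuracy bars", {
  co <- relapse_cohort(43)
  si <- stage_samples(co, "I"); siv <- stage_samples(co, "IV")
  cand <- deg_anchored_opposite_pairs(co$expression, co$expression,
                                      co$truth$deg_genes$gene,
                                      samples_iv = siv, samples_i = si, fdr = 0.01)
  ranked <- sort_relapse_candidates(
    coverage_difference(cand, co$expression, co$expression, siv, si))
  # force two blocks of strong candidates; both should pass 80%/80%
  blocks <- partition_candidates(ranked, base_size = ceiling(nrow(ranked) / 2) - 1,
                                 step = 2)
  sig <- select_relapse_signature(blocks, co$expression, co$expression, siv, si)
  grid <- sig$grid
  at <- grid[grid$cutoff == sig$vote_cutoff, ]
  passing <- at[at$acc_iv > 0.8 & at$acc_i > 0.8, ]
  expect_gt(nrow(passing), 0)
  expect_identical(sig$block_index,
                   passing$block[order(-passing$n_pairs, -passing$block)][1])
  expect_identical(nrow(sig$pairs), max(passing$n_pairs))
  # grid covers every block x cutoff combination
  expect_identical(nrow(grid), length(blocks) * 3L)
  # a single block selects itself
  single <- select_relapse_signature(blocks[1], co$expression, co$expression, siv, si)
  expect_identical(single$block_index, 1L)
})

test_that("relapse predictions are invariant to monotone per-sample transforms", {
  co <- relapse_cohort(44)
  pairs <- co$truth$relapse_pairs
  test_mat <- co$expression[, stage_samples(co, "II")]
  p0 <- predict_relapse(test_mat, pairs, cutoff = 0.49)
  expect_identical(predict_relapse(test_mat^2, pairs, cutoff = 0.49)$label, p0$label)
  expect_identical(predict_relapse(log1p(test_mat), pairs, cutoff = 0.49)$label, p0$label)
})

test_that("the built signature separates latent relapse risk in degraded samples", {
  hits <- vapply(1:10, function(seed) {
    co <- relapse_cohort(seed)
    si <- stage_samples(co, "I"); siv <- stage_samples(co, "IV")
    res <- tryCatch(
      run_relapse_pipeline(co$expression, co$phenotype, co$ff, co$ffpe,
                           co$ffpe_pairing),
      error = function(e) NULL)
    if (is.null(res)) return(0)
    mid <- c(stage_samples(co, "II"), stage_samples(co, "III"))
    degraded <- apply_ffpe_degradation(co$expression[, mid], 0.3, seed = seed + 500)
    pred <- predict(res$signature, degraded)
    m <- merge(pred, co$truth$risk_groups, by = "sample_id")
    mean(m$label == m$risk_group)
  }, numeric(1))
  expect_gte(sum(hits >= 0.8), 8)
})
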