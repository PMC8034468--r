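test_that("rank transformation uses ascending mid-ranks over measured genes", {
  expect_equal(unname(rank_transform(c(g1 = 0.5, g2 = 3.2, g3 = 1.1))), c(1, 3, 2))
  expect_equal(unname(rank_transform(c(a = 2, b = 2, c = 5))), c(1.5, 1.5, 3))
  r <- rank_transform(c(a = 4, b = NA, c = 1, d = 9))
  expect_true(is.na(r["b"]))
  expect_equal(sum(r, na.rm = TRUE), 3 * 4 / 2)  # ranks sum to n(n+1)/2
  reosig:::with_seed(5, {
    x <- stats::setNames(rexp(50), sprintf("g%02d", 1:50))
    expect_equal(sum(rank_transform(x)), 50 * 51 / 2)
  })
  expect_error(rank_transform(c(a = 1, b = NA)), "two measured")
})

test_that("rank differences are signed and antisymmetric", {
  r <- c(a = 100, b = 40, c = 40)
  expect_equal(rank_difference(r, "a", "b"), 60)
  expect_equal(rank_difference(r, "b", "c"), 0)
  expect_equal(rank_difference(r, "b", "a"), -rank_difference(r, "a", "b"))
  expect_true(is.na(rank_difference(r, "a", "zz")))
})

test_that("avgRD is the geometric mean of absolute group means of rank differences", {
  # engineered ranks: cancer RDs {+3, +5}, normal RDs {-2, -4}
  vals_for_ranks <- function(ra, rb) {
    x <- numeric(6)
    x[c(1, 2)] <- c(ra, rb) * 10
    others <- setdiff(1:6, c(ra, rb))
    x[3:6] <- others * 10
    stats::setNames(x, c("a", "b", sprintf("f%d", 1:4)))
  }
  cancer <- cbind(c1 = vals_for_ranks(5, 2), c2 = vals_for_ranks(6, 1))
  normal <- cbind(n1 = vals_for_ranks(2, 4), n2 = vals_for_ranks(1, 5))
  pairs <- data.frame(gene_a = "a", gene_b = "b")
  scored <- avg_rank_difference(pairs, cancer, normal)
  expect_equal(scored$mean_rd_cancer, 4)
  expect_equal(scored$mean_rd_normal, -3)
  expect_equal(scored$avg_rd, sqrt(12))
  # swapping the genes leaves the score unchanged
  swapped <- avg_rank_difference(data.frame(gene_a = "b", gene_b = "a"),
                                 cancer, normal)
  expect_equal(swapped$avg_rd, scored$avg_rd)
  # zero mean in one group nullifies the score
  normal0 <- cbind(n1 = vals_for_ranks(2, 4), n2 = vals_for_ranks(4, 2))
  expect_equal(avg_rank_difference(pairs, cancer, normal0)$avg_rd, 0)
})

test_that("scoring by sqrt(product) ranks pairs exactly like the plain product", {
  reosig:::with_seed(8, {
    mc <- runif(40, -50, 50)
    mn <- runif(40, -50, 50)
    expect_identical(order(sqrt(abs(mc) * abs(mn))), order(abs(mc) * abs(mn)))
  })
})

test_that("redundancy removal is greedy by score with lexicographic ties", {
  scored <- data.frame(gene_a = c("g1", "g1", "g4"),
                       gene_b = c("g2", "g3", "g5"),
                       avg_rd = c(10, 8, 6))
  kept <- remove_redundant_pairs(scored)
  expect_identical(tkey(kept$gene_a, kept$gene_b), c("g1 g2", "g4 g5"))
  # disjoint pairs all survive
  disjoint <- data.frame(gene_a = c("a", "c"), gene_b = c("b", "d"), avg_rd = c(1, 2))
  expect_identical(nrow(remove_redundant_pairs(disjoint)), 2L)
  # equal scores: lexicographically first pair wins the shared gene
  tied <- data.frame(gene_a = c("g1", "g1"), gene_b = c("g3", "g2"), avg_rd = c(5, 5))
  expect_identical(remove_redundant_pairs(tied)$gene_b, "g2")
  # output genes are pairwise distinct
  reosig:::with_seed(3, {
    big <- data.frame(gene_a = sample(letters[1:8], 20, TRUE),
                      gene_b = sample(letters[9:16], 20, TRUE),
                      avg_rd = runif(20))
    out <- remove_redundant_pairs(big)
    expect_false(anyDuplicated(c(out$gene_a, out$gene_b)) > 0)
  })
})

test_that("a noise-free planted cohort is recovered exactly and classified perfectly", {
  cfg <- sim_config(n_genes = 300, n_diag_pairs = 40, n_relapse_pairs = 10,
                    noise_sd = 0, planted_delta = 0.02, relapse_delta = 0.02,
                    seed = 17)
  co <- simulate_cohort(cfg)
  ph <- co$phenotype
  sig <- build_diagnosis_signature(
    co$expression, co$expression,
    ph$sample_id[ph$group == "cancer" & !is.na(ph$stage) & ph$stage == "I"],
    ph$sample_id[ph$group == "normal"])
  truth <- co$truth$diag_pairs
  expect_setequal(tkey(sig$pairs$gene_a, sig$pairs$gene_b),
                  tkey(truth$gene_a, truth$gene_b))
  # oriented to the cancer pattern
  expect_setequal(paste(sig$pairs$gene_a, sig$pairs$gene_b),
                  paste(truth$gene_a, truth$gene_b))
  pred <- predict(sig, co$expression)
  m <- merge(pred, ph, by = "sample_id")
  expect_true(all(m$label[m$group == "cancer"] == "CRC"))
  expect_true(all(m$label[m$group != "cancer"] == "non_cancer"))  # IBD follows normal
})

test_that("raising the stability threshold never enlarges the signature", {
  cfg <- sim_config(n_genes = 200, n_diag_pairs = 25, n_relapse_pairs = 0, seed = 31)
  co <- simulate_cohort(cfg)
  ph <- co$phenotype
  cancer <- ph$sample_id[ph$group == "cancer" & !is.na(ph$stage) & ph$stage == "I"]
  normal <- ph$sample_id[ph$group == "normal"]
  sizes <- vapply(c(0.8, 0.9, 0.95, 1), function(th) {
    nrow(find_stable_opposite_pairs(co$expression, co$expression, cancer, normal,
                                    threshold = th))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the diagnosis vote is inclusive at the cut-off and handles unmeasured signatures", {
  pairs <- data.frame(gene_a = sprintf("a%d", 1:5), gene_b = sprintf("b%d", 1:5),
                      avg_rd = 5:1)
  sig <- structure(list(pairs = pairs, vote_cutoff = 0.60, stable_threshold = 0.99,
                        n_candidates = 5L, n_cancer = 10L, n_normal = 10L),
                   class = "reo_diagnosis")
  mk <- function(n_match) {
    x <- stats::setNames(rep(1, 10), c(sprintf("a%d", 1:5), sprintf("b%d", 1:5)))
    x[sprintf("a%d", seq_len(5))] <- 0.5          # all reversed...
    if (n_match > 0) x[sprintf("a%d", seq_len(n_match))] <- 2  # ...except n_match
    x
  }
  expect_identical(classify_sample(mk(3), sig)$label, "CRC")      # 3/5 = 0.6 >= 0.6
  expect_identical(classify_sample(mk(2), sig)$label, "non_cancer")
  allna <- stats::setNames(rep(NA_real_, 10), names(mk(0)))
  expect_identical(classify_sample(allna, sig)$label, "NOT_EVALUABLE")
})

test_that("classification is invariant to monotone per-sample transforms", {
  cfg <- sim_config(n_genes = 150, n_diag_pairs = 20, n_relapse_pairs = 0, seed = 13)
  co <- simulate_cohort(cfg)
  ph <- co$phenotype
  sig <- build_diagnosis_signature(
    co$expression, co$expression,
    ph$sample_id[ph$group == "cancer" & !is.na(ph$stage) & ph$stage == "I"],
    ph$sample_id[ph$group == "normal"], stable_threshold = 0.95)
  pred0 <- predict(sig, co$expression)
  for (f in list(function(x) x^3, function(x) log1p(x), function(x) 7 * x + 1)) {
    expect_identical(predict(sig, f(co$expression))$label, pred0$label)
  }
})

test_that("accuracy tables pool counts before dividing", {
  cfg <- sim_config(n_genes = 150, n_diag_pairs = 20, n_relapse_pairs = 0,
                    noise_sd = 0, planted_delta = 0.02, seed = 2)
  co <- simulate_cohort(cfg)
  ph <- co$phenotype
  sig <- build_diagnosis_signature(
    co$expression, co$expression,
    ph$sample_id[ph$group == "cancer" & !is.na(ph$stage) & ph$stage == "I"],
    ph$sample_id[ph$group == "normal"])
  acc <- evaluate_accuracy(co$expression, ph, sig)
  expect_true(all(acc$accuracy_pct == 100))   # all-correct toy limit
  pooled <- acc[acc$dataset == "pooled", ]
  expect_setequal(pooled$group, c("cancer", "non_cancer"))
  expect_equal(pooled$n[pooled$group == "non_cancer"],
               sum(ph$group %in% c("normal", "IBD")))
  # samples without phenotype are excluded with a warning
  expect_warning(evaluate_accuracy(co$expression, ph[-1, ], sig), "without phenotype")
  # pooling helper does exact count arithmetic
  expect_equal(pool_accuracy(c(9, 1), c(10, 10)), 50)
  expect_error(pool_accuracy(2, 1), "exceed")
})
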