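test_that("the order relation handles zeros, ties and missing values", {
  expect_identical(reo_sign(5.0, 3.0), "GREATER")
  expect_identical(reo_sign(3.0, 5.0), "LESS")
  expect_identical(reo_sign(2.0, 2.0), "TIE")
  expect_identical(reo_sign(0.0, 0.0), "NOT_EVALUABLE")   # nothing detected
  expect_identical(reo_sign(0.0, 2.0), "LESS")            # one zero is evaluable
  expect_identical(reo_sign(NA, 2.0), "NOT_EVALUABLE")
  expect_identical(reo_sign(c(1, 0), c(0, 0)), c("GREATER", "NOT_EVALUABLE"))
  expect_error(reo_sign(-1, 2), "nonnegative")
})

test_that("pattern frequency counts only evaluable samples and ties count against", {
  m <- make_mat(rbind(a = c(5, 4, 1), b = c(3, 3, 2)), genes = c("a", "b"))
  f <- pair_pattern_frequency(m, "a", "b")
  expect_equal(f$freq, 2 / 3)
  expect_identical(f$n_evaluable, 3L)

  m2 <- make_mat(rbind(c(5, 0), c(3, 0)), genes = c("a", "b"))
  f2 <- pair_pattern_frequency(m2, "a", "b")
  expect_equal(f2$freq, 1)          # both-zero sample excluded
  expect_identical(f2$n_evaluable, 1L)

  m3 <- make_mat(rbind(c(2, 2), c(2, 2)), genes = c("a", "b"))
  f3 <- pair_pattern_frequency(m3, "a", "b")
  expect_equal(f3$freq, 0)          # ties evaluable, never matching

  m4 <- make_mat(rbind(c(0, NA), c(0, 1)), genes = c("a", "b"))
  f4 <- pair_pattern_frequency(m4, "a", "b")
  expect_false(f4$evaluable)        # no evaluable sample: a result, not an error
})

test_that("stable pairs honour the inclusive threshold boundary", {
  build <- function(n_greater, n_total) {
    a <- c(rep(2, n_greater), rep(1, n_total - n_greater))
    b <- c(rep(1, n_greater), rep(2, n_total - n_greater))
    make_mat(rbind(a, b), genes = c("a", "b"))
  }
  expect_identical(nrow(find_stable_pairs(build(20, 20), threshold = 0.95)), 1L)
  at_boundary <- find_stable_pairs(build(19, 20), threshold = 0.95)
  expect_identical(nrow(at_boundary), 1L)   # 19/20 = 0.95 is included
  expect_equal(at_boundary$freq, 0.95)
  expect_identical(nrow(find_stable_pairs(build(18, 20), threshold = 0.95)), 0L)
  # majority orientation
  flipped <- find_stable_pairs(build(0, 20), threshold = 0.95)
  expect_identical(flipped$gene_a, "b")
  expect_error(find_stable_pairs(build(20, 20), threshold = 0.5), "0.5")
})

test_that("stable-pair sets shrink as the threshold rises", {
  sim <- planted_reversal_mat(n_per_group = 25, n_null_genes = 15, seed = 42)
  sets <- lapply(c(0.7, 0.85, 0.95, 1), function(th) {
    s <- find_stable_pairs(sim$mat, sim$ref, threshold = th)
    tkey(s$gene_a, s$gene_b)
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("stable opposite pairs are oriented to the reference group and antisymmetric", {
  a <- c(5, 5, 5, 1, 1, 1)
  b <- c(2, 2, 2, 4, 4, 4)
  m <- make_mat(rbind(a, b), genes = c("a", "b"))
  ref <- paste0("s", 1:3); oth <- paste0("s", 4:6)
  fwd <- find_stable_opposite_pairs(m, m, ref, oth, threshold = 0.95)
  expect_identical(fwd[, c("gene_a", "gene_b")],
                   data.frame(gene_a = "a", gene_b = "b"))
  swapped <- find_stable_opposite_pairs(m, m, oth, ref, threshold = 0.95)
  expect_identical(swapped$gene_a, "b")   # exchanging groups maps (a,b) to (b,a)
  # same direction in both groups: nothing
  same <- find_stable_opposite_pairs(m, m, ref, ref, threshold = 0.95)
  expect_identical(nrow(same), 0L)
})

test_that("the reversal p-value equals exhaustive hypergeometric enumeration", {
  # fully reversed 3 vs 3: single extreme table
  expect_equal(opposite_pair_pvalue(3, 0, 3, 3), choose(3, 3) * choose(3, 0) / choose(6, 3))
  expect_equal(opposite_pair_pvalue(3, 0, 3, 3), 0.05)
  # null: both groups half reversed
  expect_gte(opposite_pair_pvalue(10, 5, 10, 5), 0.5)
  expect_equal(opposite_pair_pvalue(0, 0, 0, 0), 1)
  expect_error(opposite_pair_pvalue(3, 4, 3, 0), "exceed")

  for (n_ref in c(1, 3, 7, 12)) {
    for (n_oth in c(1, 4, 12)) {
      for (k_ref in 0:n_ref) {
        for (k_oth in 0:n_oth) {
          expect_equal(opposite_pair_pvalue(n_ref, k_ref, n_oth, k_oth),
                       oracle_hyper_tail(n_ref, k_ref, n_oth, k_oth),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  reosig:::with_seed(11, {
    for (i in 1:5) {
      p <- runif(50)^2
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significant opposite pairs find a planted reversal and grow with the FDR", {
  sim <- planted_reversal_mat(n_per_group = 30, n_null_genes = 20, seed = 3)
  hits <- find_significant_opposite_pairs(sim$mat, sim$mat, sim$ref, sim$other,
                                          fdr = 0.05)
  expect_true("pa pb" %in% tkey(hits$gene_a, hits$gene_b))
  planted <- hits[tkey(hits$gene_a, hits$gene_b) == "pa pb", ]
  expect_identical(planted$gene_a, "pa")  # oriented to the reference majority
  loose <- find_significant_opposite_pairs(sim$mat, sim$mat, sim$ref, sim$other,
                                           fdr = 0.999)
  expect_true(all(tkey(hits$gene_a, hits$gene_b) %in% tkey(loose$gene_a, loose$gene_b)))
})

test_that("retention rate applies the evaluability rules of the voting statistic", {
  pairs <- data.frame(gene_a = c("a", "c", "e", "g"),
                      gene_b = c("b", "d", "f", "h"))
  x <- c(a = 5, b = 1, c = 4, d = 2, e = 3, f = 1, g = 1, h = 6)
  r <- retention_rate(x, pairs)
  expect_identical(c(r$k, r$m), c(3L, 4L))
  expect_equal(r$ratio, 0.75)

  # a both-zero pair drops out of the denominator
  x2 <- c(a = 5, b = 1, c = 4, d = 2, e = 3, f = 1, g = 0, h = 0)
  r2 <- retention_rate(x2, pairs)
  expect_identical(c(r2$k, r2$m), c(3L, 3L))
  expect_equal(r2$ratio, 1.0)

  # unmeasured genes remove their pairs; none left -> not evaluable
  x3 <- c(a = NA, b = 1, c = NA, d = 2)
  r3 <- retention_rate(x3, pairs)
  expect_identical(r3$m, 0L)
  expect_false(r3$evaluable)
  expect_true(is.na(r3$ratio))
})

test_that("retention declines with dropout while self-retention of clean data is perfect", {
  cfg <- sim_config(n_genes = 200, n_diag_pairs = 30, n_relapse_pairs = 0,
                    noise_sd = 0, seed = 21)
  co <- simulate_cohort(cfg)
  ph <- co$phenotype
  cancer <- ph$sample_id[ph$group == "cancer"]
  pairs <- co$truth$diag_pairs
  clean <- retention_rates(co$expression, pairs, cancer)
  expect_true(all(clean$ratio == 1))      # noise-free cancer keeps its own pattern
  rates <- vapply(c(0, 0.2, 0.4, 0.54), function(d) {
    mean(vapply(1:5, function(s) {
      deg <- apply_ffpe_degradation(co$expression[, cancer], d, seed = 100 * s + d * 100)
      mean(retention_rates(deg, pairs)$ratio, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) < 0))       # monotone decline over dropout levels
})
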