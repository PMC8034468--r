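# reosig

Qualitative transcriptional signatures for low-quality clinical samples,
built from within-sample **relative expression orderings** (REOs) of gene
pairs.

## Why

Archived clinical material — FFPE blocks stored for years at room
temperature — yields degraded, zero-inflated RNA-seq profiles (RIN ≈ 2,
28–54% of genes measured as zero) on which expression-level risk scores
fail. The *ordering* of two genes' abundances within one sample, however, is
invariant to monotone distortions and survives degradation far better than
the measurements themselves. `reosig` implements signatures made of
**hundreds to thousands of oriented gene pairs** voted by a retention rate,
so that the silencing of any individual gene barely moves the vote:

- **Early-diagnosis classifier** (colorectal cancer vs normal/IBD): stable
  opposite pairs between the training groups, scored by the geometric mean
  of absolute mean within-sample rank differences,
  `avgRD = sqrt(|mean RD(cancer)| · |mean RD(normal)|)`, de-duplicated so no
  gene appears twice; a sample is called cancer when the fraction of
  evaluable signature pairs showing the cancer pattern `G_i > G_j` is ≥ 60%.
- **Relapse-risk predictor** (post-surgery stage II/III): significant
  opposite pairs between stage IV and stage I anchored at rank-based DEGs
  (single-pass RankComp-style caller: binomial-stable pairs, gene-level
  Fisher 2×2), filtered by FF/FFPE ordering concordance in ≥ 10 paired
  samples, ranked by the coverage difference `C_IV − C_I`, partitioned into
  blocks of 3500 + 1000·(n−1) pairs, with the block and cut-off (49/50/51%)
  chosen on training accuracy; high risk when the retention rate is
  strictly > 49%.
- **Reversal testing**: pooled-margin cumulative hypergeometric tail for
  pattern reversal between groups, BH FDR control throughout.
- **Survival evaluation**: Kaplan–Meier, log-rank, Cox proportional hazards
  (Efron ties), Schoenfeld residual diagnostics, follow-up horizons.
- **Synthetic cohorts**: a fully seeded generator planting reversed pairs,
  stage-linked coverage gaps, latent relapse risk, biased FFPE dropout,
  purity mixing, paired FF/FFPE samples and censored relapse times, with
  complete ground truth for parameter-recovery testing.

Evaluability rules used everywhere: a pair is dropped in a sample when both
genes are zero or either is unmeasured; one zero is evaluable; ties match
neither pattern.

## Worked example

```r
library(reosig)

cohort <- simulate_cohort(sim_config(seed = 1))   # 600 genes, 240 samples
ph <- cohort$phenotype

sig <- build_diagnosis_signature(
  cohort$expression, cohort$expression,
  samples_cancer = ph$sample_id[ph$group == "cancer" & !is.na(ph$stage) & ph$stage == "I"],
  samples_normal = ph$sample_id[ph$group == "normal"],
  stable_threshold = 0.95)
print(sig)
#> REO early-diagnosis signature
#>   131 gene pairs (from 2593 stable opposite pairs at 95% stability)
#>   voting rule: cancer iff retention rate >= 60%
#>   trained on 40 cancer / 40 normal samples

# apply to FFPE-like degraded copies of the cohort (35% zeros)
ffpe_like <- apply_ffpe_degradation(cohort$expression, dropout_rate = 0.35, seed = 2)
head(predict(sig, ffpe_like), 4)
#>   sample_id  k   m     ratio      label
#> 1       N01 26 119 0.2184874 non_cancer
#> 2       N02 28 124 0.2258065 non_cancer
#> 3       N03 33 123 0.2682927 non_cancer
#> 4       N04 24 123 0.1951220 non_cancer
```

A normal sample retains only ~22% of the cancer-oriented pairs — far below
the 60% cut-off — even with a third of the genes zeroed; cancer samples stay
near 80%. Pooled accuracy on the degraded cohort:

```r
acc <- evaluate_accuracy(ffpe_like, ph, sig)
acc[acc$dataset == "pooled", ]
#>   dataset      group   n n_correct accuracy_pct
#> 4  pooled     cancer 160       160          100
#> 5  pooled non_cancer  80        80          100
```

The relapse pipeline runs end to end from the same cohort (DEG calling,
anchored reversed pairs, FF/FFPE concordance filter, coverage ranking,
block/cut-off selection, prediction, survival report):

```r
relapse <- run_relapse_pipeline(cohort$expression, ph, cohort$ff, cohort$ffpe,
                                cohort$ffpe_pairing,
                                survival_records = cohort$survival)
print(relapse$signature)
#> REO relapse-risk signature
#>   3500 gene pairs (candidate block 1)
#>   voting rule: high risk iff retention rate > 49%
#>   training accuracy: stage I 100.0%, stage IV 100.0% (n = 40 / 40)
print(relapse$survival_report$cox)
#> Cox proportional-hazards fit (80 records, 59 events)
#>                 term   hr        ci p_value
#>  risk_grouphigh_risk 1.80 1.07-3.03  0.0266
```

Predicted high-risk stage II/III patients relapse ~1.8× faster than
low-risk ones in this small simulated cohort (true latent hazard ratio 3;
the point estimate is attenuated by classification error at n = 80).

See `vignettes/reo-signatures.Rmd` for the model, every tunable parameter,
the generator's design and its limitations.

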