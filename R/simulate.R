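#' Configuration for a synthetic CRC cohort
#'
#' Collects every tunable of the cohort generator with defaults chosen to
#' mirror the data regime the signatures are designed for: log-normal
#' FPKM-like abundances, planted reversed gene pairs between cancer and
#' normal (the IBD group follows the normal pattern), relapse-linked pairs
#' whose pattern frequency is higher in stage IV and in latent high-risk
#' stage II/III samples than in stage I, FFPE degradation with
#' low-expression-biased dropout, paired FF/FFPE samples, and exponential
#' relapse times with censoring.
#'
#' @param n_genes Number of genes.
#' @param n_normal,n_ibd Normal and IBD group sizes.
#' @param n_stage Named integer vector of cancer group sizes per stage
#'   (`I`, `II`, `III`, `IV`).
#' @param n_diag_pairs Planted diagnosis pairs (reversed between cancer and
#'   normal).
#' @param n_relapse_pairs Planted relapse pairs (pattern frequency gap
#'   between stage IV/high-risk and stage I/low-risk).
#' @param planted_delta Log-scale separation of a planted diagnosis pair's
#'   two genes (the swap magnitude between groups).
#' @param relapse_delta Same for relapse pairs.
#' @param pattern_freq_low Relapse-pattern probability in stage I / latent
#'   low-risk samples.
#' @param coverage_gap Increase of that probability in stage IV / latent
#'   high-risk samples (the planted coverage difference).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline of gene
#'   abundances.
#' @param noise_sd Per-sample log-scale measurement noise.
#' @param ibd_sd Log-scale perturbation of background genes in the IBD group
#'   (planted pairs are left untouched so IBD keeps the normal pattern).
#' @param dropout_rate Target zero fraction of FFPE degradation.
#' @param dropout_bias Logistic slope of dropout in log-expression (0 =
#'   uniform dropout).
#' @param degradation_noise_sd Extra log-normal noise on surviving values of
#'   degraded samples.
#' @param purity_range Range of the tumour-cell fraction of cancer samples;
#'   `c(1, 1)` (default) models research-grade, purity-selected material.
#' @param frac_high_risk Fraction of stage II/III samples carrying the latent
#'   high-risk (micro-metastatic) pattern.
#' @param n_ff_ffpe_pairs Number of paired FF/FFPE samples.
#' @param baseline_hazard Relapse hazard per month of the low-risk group.
#' @param true_hr Hazard ratio of the high-risk group.
#' @param censoring_rate Target fraction of censored follow-up records.
#' @param seed RNG seed fixing the whole cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 600,
                       n_normal = 40, n_ibd = 40,
                       n_stage = c(I = 40, II = 40, III = 40, IV = 40),
                       n_diag_pairs = 136, n_relapse_pairs = 40,
                       planted_delta = 0.7, relapse_delta = 2,
                       pattern_freq_low = 0.25, coverage_gap = 0.5,
                       baseline_meanlog = 1.5, baseline_sdlog = 2,
                       noise_sd = 0.2, ibd_sd = 0.3,
                       dropout_rate = 0.35, dropout_bias = 1,
                       degradation_noise_sd = 0.5,
                       purity_range = c(1, 1),
                       frac_high_risk = 0.45,
                       n_ff_ffpe_pairs = 13,
                       baseline_hazard = 0.02, true_hr = 3,
                       censoring_rate = 0.3,
                       seed = 1) {
  cfg <- as.list(environment())
  rates <- c(pattern_freq_low, coverage_gap, dropout_rate, frac_high_risk,
             censoring_rate, purity_range)
  if (any(rates < 0 | rates > 1)) stop("rates and purities must be in [0, 1]")
  if (pattern_freq_low + coverage_gap > 1) {
    stop("pattern_freq_low + coverage_gap must not exceed 1")
  }
  if (any(c(n_genes, n_normal, n_ibd, n_stage) <= 0)) stop("sizes must be positive")
  if (!all(c("I", "II", "III", "IV") %in% names(n_stage))) {
    stop("n_stage must name stages I-IV")
  }
  n_pairs <- n_diag_pairs + n_relapse_pairs
  if (n_pairs > floor(n_genes / 2)) {
    stop("more planted pairs than floor(n_genes / 2)")
  }
  if (2 * n_pairs > floor(0.7 * n_genes)) {
    stop("planted genes exceed the mid-expression band (~70% of ", n_genes, " genes)")
  }
  if (true_hr <= 0) stop("true_hr must be positive")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d genes; groups: %d normal, %d IBD, stages %s\n",
              x$n_genes, x$n_normal, x$n_ibd,
              paste(names(x$n_stage), x$n_stage, sep = "=", collapse = " ")))
  cat(sprintf("  planted: %d diagnosis pairs (delta %.2f), %d relapse pairs (gap %.2f)\n",
              x$n_diag_pairs, x$planted_delta, x$n_relapse_pairs, x$coverage_gap))
  cat(sprintf("  noise_sd %.2f; FFPE dropout %.2f; seed %d\n",
              x$noise_sd, x$dropout_rate, x$seed))
  invisible(x)
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Generates expression (research-grade; apply [apply_ffpe_degradation()] to
#' emulate FFPE material), phenotypes, paired FF/FFPE samples and
#' relapse-linked survival, all deterministically under the config seed.
#'
#' Structure: every gene has a log-normal baseline. Each planted diagnosis
#' pair occupies a narrow window around a centre on the log scale -- the two
#' genes swap ends of the window between the cancer and normal/IBD groups, so
#' the pair's ordering reverses while the genes' orderings relative to genes
#' outside the window are preserved. Pair centres are spread evenly over the
#' mid-expression band; when the window width exceeds the centre spacing,
#' neighbouring windows overlap and additional reversed pairs sharing planted
#' genes arise, as in real data. Relapse pairs swap per sample, with the
#' relapse pattern drawn at probability `pattern_freq_low` in stage I and
#' latent low-risk samples and `pattern_freq_low + coverage_gap` in stage IV
#' and latent high-risk samples.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `reo_cohort`: `expression` (genes x samples),
#'   `phenotype`, `survival` (stage II/III records with latent risk),
#'   `ff`, `ffpe`, `ffpe_pairing`, `truth` (planted `diag_pairs`,
#'   `relapse_pairs`, `deg_genes`, `risk_groups`, `purity`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  G <- cfg$n_genes
  genes <- sprintf("g%04d", seq_len(G))
  mu0 <- stats::rnorm(G, cfg$baseline_meanlog, cfg$baseline_sdlog)
  names(mu0) <- genes

  # planted genes live in the mid-expression band where degradation dropout
  # is moderate; centres are spread evenly so windows are as disjoint as the
  # pair count allows
  n_pairs <- cfg$n_diag_pairs + cfg$n_relapse_pairs
  band <- genes[mu0 >= stats::quantile(mu0, 0.25) & mu0 <= stats::quantile(mu0, 0.95)]
  planted <- sample(band, 2 * n_pairs)
  lo <- stats::quantile(mu0[band], 0.05)
  hi <- stats::quantile(mu0[band], 0.95)
  centres <- if (n_pairs > 1) seq(lo, hi, length.out = n_pairs) else mean(c(lo, hi))
  centres <- sample(centres)

  diag_pairs <- relapse_pairs <- NULL
  if (cfg$n_diag_pairs > 0) {
    diag_pairs <- data.frame(
      gene_a = planted[seq_len(cfg$n_diag_pairs)],
      gene_b = planted[cfg$n_diag_pairs + seq_len(cfg$n_diag_pairs)],
      centre = centres[seq_len(cfg$n_diag_pairs)],
      stringsAsFactors = FALSE)
  }
  if (cfg$n_relapse_pairs > 0) {
    off <- 2 * cfg$n_diag_pairs
    relapse_pairs <- data.frame(
      gene_a = planted[off + seq_len(cfg$n_relapse_pairs)],
      gene_b = planted[off + cfg$n_relapse_pairs + seq_len(cfg$n_relapse_pairs)],
      centre = centres[cfg$n_diag_pairs + seq_len(cfg$n_relapse_pairs)],
      stringsAsFactors = FALSE)
  }

  half_d <- cfg$planted_delta / 2
  half_r <- cfg$relapse_delta / 2

  mu_normal <- mu0
  if (!is.null(diag_pairs)) {
    mu_normal[diag_pairs$gene_a] <- diag_pairs$centre - half_d
    mu_normal[diag_pairs$gene_b] <- diag_pairs$centre + half_d
  }
  if (!is.null(relapse_pairs)) {  # relapse pattern off outside cancer
    mu_normal[relapse_pairs$gene_a] <- relapse_pairs$centre - half_r
    mu_normal[relapse_pairs$gene_b] <- relapse_pairs$centre + half_r
  }
  mu_cancer <- mu_normal
  if (!is.null(diag_pairs)) {
    mu_cancer[diag_pairs$gene_a] <- diag_pairs$centre + half_d
    mu_cancer[diag_pairs$gene_b] <- diag_pairs$centre - half_d
  }
  mu_ibd <- mu_normal
  background <- setdiff(genes, planted)
  mu_ibd[background] <- mu_ibd[background] +
    stats::rnorm(length(background), 0, cfg$ibd_sd)

  # sample layout
  stages <- rep(names(cfg$n_stage), cfg$n_stage)
  ids_normal <- sprintf("N%02d", seq_len(cfg$n_normal))
  ids_ibd <- sprintf("IBD%02d", seq_len(cfg$n_ibd))
  ids_cancer <- unlist(lapply(names(cfg$n_stage), function(st) {
    sprintf("CRC_%s_%02d", st, seq_len(cfg$n_stage[[st]]))
  }))
  risk <- rep(NA_character_, length(ids_cancer))
  risk[stages == "I"] <- "low_risk"
  risk[stages == "IV"] <- "high_risk"
  mid <- stages %in% c("II", "III")
  risk[mid] <- ifelse(stats::runif(sum(mid)) < cfg$frac_high_risk,
                      "high_risk", "low_risk")

  p_on <- ifelse(risk == "high_risk",
                 cfg$pattern_freq_low + cfg$coverage_gap, cfg$pattern_freq_low)

  draw_sample <- function(mu) exp(mu + stats::rnorm(G, 0, cfg$noise_sd))

  cancer_col <- function(p_pattern) {
    mu <- mu_cancer
    if (!is.null(relapse_pairs)) {
      on <- stats::runif(nrow(relapse_pairs)) < p_pattern
      mu[relapse_pairs$gene_a] <- relapse_pairs$centre + ifelse(on, half_r, -half_r)
      mu[relapse_pairs$gene_b] <- relapse_pairs$centre + ifelse(on, -half_r, half_r)
    }
    draw_sample(mu)
  }

  expr <- matrix(NA_real_, nrow = G,
                 ncol = length(ids_normal) + length(ids_ibd) + length(ids_cancer),
                 dimnames = list(genes, c(ids_normal, ids_ibd, ids_cancer)))
  for (s in ids_normal) expr[, s] <- draw_sample(mu_normal)
  for (s in ids_ibd) expr[, s] <- draw_sample(mu_ibd)
  for (i in seq_along(ids_cancer)) expr[, ids_cancer[i]] <- cancer_col(p_on[i])

  purity <- rep(1, length(ids_cancer))
  if (diff(range(cfg$purity_range)) > 0 || cfg$purity_range[1] < 1) {
    purity <- stats::runif(length(ids_cancer), min(cfg$purity_range), max(cfg$purity_range))
    normal_ref <- exp(mu_normal)
    for (i in seq_along(ids_cancer)) {
      expr[, ids_cancer[i]] <- mix_purity(expr[, ids_cancer[i]], normal_ref, purity[i])
    }
  }

  # paired FF/FFPE samples: stage II-like tumours, FFPE copies degraded
  ff <- ffpe <- NULL
  ffpe_pairing <- data.frame(ff = character(0), ffpe = character(0))
  if (cfg$n_ff_ffpe_pairs > 0) {
    risk_ff <- ifelse(stats::runif(cfg$n_ff_ffpe_pairs) < cfg$frac_high_risk,
                      cfg$pattern_freq_low + cfg$coverage_gap, cfg$pattern_freq_low)
    ff <- vapply(risk_ff, cancer_col, numeric(G))
    dimnames(ff) <- list(genes, sprintf("FF%02d", seq_len(cfg$n_ff_ffpe_pairs)))
    ffpe <- degrade_impl(ff, cfg$dropout_rate, cfg$dropout_bias,
                         cfg$degradation_noise_sd)
    colnames(ffpe) <- sprintf("FFPE%02d", seq_len(cfg$n_ff_ffpe_pairs))
    ffpe_pairing <- data.frame(ff = colnames(ff), ffpe = colnames(ffpe),
                               stringsAsFactors = FALSE)
  }

  # relapse-linked follow-up for stage II/III patients
  surv_ids <- ids_cancer[mid]
  survival_records <- NULL
  if (length(surv_ids) > 0) {
    rg <- risk[mid]
    names(rg) <- surv_ids
    survival_records <- survival_impl(rg, cfg$baseline_hazard, cfg$true_hr,
                                      cfg$censoring_rate)
  }

  phenotype <- data.frame(
    sample_id = c(ids_normal, ids_ibd, ids_cancer),
    group = c(rep("normal", length(ids_normal)), rep("IBD", length(ids_ibd)),
              rep("cancer", length(ids_cancer))),
    stage = c(rep(NA_character_, length(ids_normal) + length(ids_ibd)), stages),
    stringsAsFactors = FALSE)
  phenotype$relapse <- NA_character_
  if (!is.null(survival_records)) {
    m <- match(phenotype$sample_id, survival_records$sample_id)
    phenotype$relapse <- ifelse(is.na(m), NA_character_,
                                ifelse(survival_records$event[m] == 1,
                                       "relapse", "non_relapse"))
  }

  deg_genes <- if (is.null(relapse_pairs)) {
    data.frame(gene = character(0), direction = character(0))
  } else {
    data.frame(gene = c(relapse_pairs$gene_a, relapse_pairs$gene_b),
               direction = rep(c("up", "down"), each = nrow(relapse_pairs)),
               stringsAsFactors = FALSE)
  }

  structure(list(
    expression = expr,
    phenotype = phenotype,
    survival = survival_records,
    ff = ff, ffpe = ffpe, ffpe_pairing = ffpe_pairing,
    truth = list(
      diag_pairs = if (is.null(diag_pairs)) empty_pairs() else
        diag_pairs[, c("gene_a", "gene_b")],
      relapse_pairs = if (is.null(relapse_pairs)) empty_pairs() else
        relapse_pairs[, c("gene_a", "gene_b")],
      deg_genes = deg_genes,
      risk_groups = data.frame(sample_id = ids_cancer, stage = stages,
                               risk_group = risk, stringsAsFactors = FALSE),
      purity = data.frame(sample_id = ids_cancer, purity = purity,
                          stringsAsFactors = FALSE)
    ),
    config = cfg
  ), class = "reo_cohort")
}

#' @export
print.reo_cohort <- function(x, ...) {
  cat("Synthetic REO cohort\n")
  cat(sprintf("  expression: %d genes x %d samples (+ %d FF/FFPE pairs)\n",
              nrow(x$expression), ncol(x$expression), nrow(x$ffpe_pairing)))
  cat(sprintf("  planted: %d diagnosis pairs, %d relapse pairs\n",
              nrow(x$truth$diag_pairs), nrow(x$truth$relapse_pairs)))
  cat(sprintf("  seed %d\n", x$config$seed))
  invisible(x)
}

#' Degrade an expression matrix as FFPE preservation would
#'
#' Sets entries to zero with a probability that increases as expression
#' decreases (logistic in log-expression with slope `bias_strength`; 0 gives
#' uniform dropout), calibrated so the expected zero fraction over measured
#' entries equals `dropout_rate`; entries that are already zero count towards
#' that fraction. Surviving positive values are multiplied by log-normal
#' noise. With `dropout_rate = 0` and `noise_sd = 0` the matrix is returned
#' unchanged.
#'
#' @param mat Expression matrix.
#' @param dropout_rate Target zero fraction in \[0, 1\].
#' @param bias_strength Logistic slope of dropout vs log-expression.
#' @param noise_sd Log-scale sd of the multiplicative noise.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The degraded matrix.
#' @export
apply_ffpe_degradation <- function(mat, dropout_rate, bias_strength = 1,
                                   noise_sd = 0.5, seed = NULL) {
  validate_expression_matrix(mat)
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (is.null(seed)) degrade_impl(mat, dropout_rate, bias_strength, noise_sd)
  else with_seed(seed, degrade_impl(mat, dropout_rate, bias_strength, noise_sd))
}

degrade_impl <- function(mat, dropout_rate, bias_strength, noise_sd) {
  measured <- !is.na(mat)
  vals <- mat[measured]
  zero_frac0 <- mean(vals == 0)
  if (dropout_rate > zero_frac0) {
    pos <- vals > 0
    mean_p_pos <- (dropout_rate - zero_frac0) / (1 - zero_frac0)
    lx <- log(vals[pos])
    if (bias_strength <= 0) {
      p <- rep(mean_p_pos, sum(pos))
    } else {
      # calibrate the logistic midpoint so the average dropout hits the target
      f <- function(cc) mean(stats::plogis(bias_strength * (cc - lx))) - mean_p_pos
      cc <- stats::uniroot(f, lower = min(lx) - 50 / bias_strength,
                           upper = max(lx) + 50 / bias_strength)$root
      p <- stats::plogis(bias_strength * (cc - lx))
    }
    dropped <- stats::runif(sum(pos)) < p
    v <- vals[pos]
    v[dropped] <- 0
    vals[pos] <- v
  }
  if (noise_sd > 0) {
    pos2 <- vals > 0
    vals[pos2] <- vals[pos2] * exp(stats::rnorm(sum(pos2), 0, noise_sd))
  }
  out <- mat
  out[measured] <- vals
  out
}

#' Mix a tumour profile with a normal profile
#'
#' Convex combination `alpha * tumor + (1 - alpha) * normal` per gene,
#' modelling bulk samples of tumour fraction `alpha` (no pre-purification).
#'
#' @param tumor,normal Named numeric vectors (or single-column matrices) over
#'   the same gene universe.
#' @param alpha Tumour fraction in \[0, 1\].
#' @return Named numeric vector of the mixed profile.
#' @export
mix_purity <- function(tumor, normal, alpha) {
  tumor <- drop(tumor); normal <- drop(normal)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (is.null(names(tumor)) || is.null(names(normal)) ||
      !identical(names(tumor), names(normal))) {
    stop("tumor and normal profiles must share an identical gene universe")
  }
  alpha * tumor + (1 - alpha) * normal
}

#' Simulate relapse-linked survival records
#'
#' Exponential event times with hazard `baseline_hazard` in the low-risk
#' group and `baseline_hazard * true_hr` in the high-risk group; independent
#' uniform censoring with its upper bound calibrated numerically so that the
#' expected censored fraction equals `censoring_rate` (0 = no censoring).
#'
#' @param risk_groups Character vector of `"high_risk"` / `"low_risk"`,
#'   named by sample id.
#' @param baseline_hazard Low-risk hazard per time unit.
#' @param true_hr Hazard ratio (> 0).
#' @param censoring_rate Target censored fraction in \[0, 1).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Data frame (`sample_id`, `time`, `event`, `risk_group`).
#' @export
simulate_survival <- function(risk_groups, baseline_hazard = 0.02, true_hr = 3,
                              censoring_rate = 0.3, seed = NULL) {
  if (true_hr <= 0) stop("true_hr must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) stop("censoring_rate must be in [0, 1)")
  if (is.null(seed)) survival_impl(risk_groups, baseline_hazard, true_hr, censoring_rate)
  else with_seed(seed, survival_impl(risk_groups, baseline_hazard, true_hr, censoring_rate))
}

survival_impl <- function(risk_groups, baseline_hazard, true_hr, censoring_rate) {
  n <- length(risk_groups)
  ids <- names(risk_groups) %||% sprintf("S%03d", seq_len(n))
  h <- ifelse(risk_groups == "high_risk", baseline_hazard * true_hr, baseline_hazard)
  t_event <- stats::rexp(n, h)
  if (censoring_rate <= 0) {
    time <- t_event
    event <- rep(1L, n)
  } else {
    # E[P(C < T)] for C ~ U(0, u): mean over subjects of (1 - exp(-h u))/(h u)
    f <- function(u) mean((1 - exp(-h * u)) / (h * u)) - censoring_rate
    u <- stats::uniroot(f, lower = 1e-8, upper = 1e8)$root
    cens <- stats::runif(n, 0, u)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
  }
  data.frame(sample_id = ids, time = time, event = event,
             risk_group = unname(risk_groups), stringsAsFactors = FALSE,
             row.names = NULL)
}
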