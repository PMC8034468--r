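# End-to-end orchestration: simulate/ingest -> build -> classify -> evaluate,
# with a run manifest (stage counts and timings) so every filtering step's
# input/output sizes are auditable for any dataset.

run_stage <- function(manifest, name, n_in, expr) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  n_out <- if (is.data.frame(result) || is.matrix(result)) nrow(result)
  else if (is.list(result) && !is.null(result$pairs)) nrow(result$pairs)
  else length(result)
  manifest$stages[[name]] <- list(n_in = n_in, n_out = n_out,
                                  seconds = round(proc.time()[["elapsed"]] - t0, 3))
  list(manifest = manifest, result = result)
}

new_manifest <- function(params) {
  list(tool = "reosig",
       version = as.character(utils::packageVersion("reosig")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       params = params,
       stages = list())
}

#' Run the early-diagnosis pipeline end to end
#'
#' Stable-opposite-pair discovery, rank-difference scoring, redundancy
#' removal, classification of every sample and an accuracy table, with a run
#' manifest recording per-stage input/output counts and timings. Each stage
#' failure aborts with the stage name.
#'
#' @param expression Expression matrix holding both training and test
#'   samples.
#' @param phenotype Phenotype table covering the samples.
#' @param train_cancer,train_normal Sample ids of the training groups;
#'   defaults: stage I cancer samples and all normal samples.
#' @param stable_threshold,vote_cutoff Passed to
#'   [build_diagnosis_signature()].
#' @param out_dir Optional directory; when given, the signature, predictions,
#'   accuracy table and manifest are written there.
#' @return List with `signature`, `predictions`, `accuracy`, `manifest`.
#' @export
run_diagnosis_pipeline <- function(expression, phenotype,
                                   train_cancer = NULL, train_normal = NULL,
                                   stable_threshold = 0.99, vote_cutoff = 0.60,
                                   out_dir = NULL) {
  manifest <- new_manifest(list(stable_threshold = stable_threshold,
                                vote_cutoff = vote_cutoff))
  st <- run_stage(manifest, "inputs", ncol(expression), {
    validate_expression_matrix(expression)
    phenotype <- validate_phenotype_table(phenotype)
    missing <- setdiff(colnames(expression), phenotype$sample_id)
    if (is.null(train_cancer)) {
      train_cancer <- phenotype$sample_id[phenotype$group == "cancer" &
                                            !is.na(phenotype$stage) &
                                            phenotype$stage == "I"]
    }
    if (is.null(train_normal)) {
      train_normal <- phenotype$sample_id[phenotype$group == "normal"]
    }
    if (length(train_cancer) == 0 || length(train_normal) == 0) {
      stop("empty training group")
    }
    phenotype
  })
  manifest <- st$manifest; phenotype <- st$result

  st <- run_stage(manifest, "signature", length(train_cancer) + length(train_normal),
                  build_diagnosis_signature(expression, expression,
                                            train_cancer, train_normal,
                                            stable_threshold = stable_threshold,
                                            vote_cutoff = vote_cutoff))
  manifest <- st$manifest; signature <- st$result

  st <- run_stage(manifest, "classify", ncol(expression),
                  predict(signature, expression))
  manifest <- st$manifest; predictions <- st$result

  st <- run_stage(manifest, "evaluate", nrow(predictions),
                  evaluate_accuracy(expression, phenotype, signature))
  manifest <- st$manifest; accuracy <- st$result

  out <- list(signature = signature, predictions = predictions,
              accuracy = accuracy, manifest = manifest)
  if (!is.null(out_dir)) persist_outputs(out_dir, list(
    diagnosis_signature.tsv = signature$pairs,
    diagnosis_predictions.csv = predictions,
    diagnosis_accuracy.csv = accuracy), manifest, "diagnosis_manifest.json")
  out
}

#' Run the relapse-prediction pipeline end to end
#'
#' Rank-comparison DEGs between stage I and IV, DEG-anchored significant
#' opposite pairs, paired FF/FFPE concordance filtering, coverage-difference
#' ranking, candidate partitioning, cut-off/candidate selection, relapse
#' prediction for stage II/III samples and (when follow-up records are
#' supplied) a survival report.
#'
#' @param expression Expression matrix holding the cancer samples.
#' @param phenotype Phenotype table with `stage` for cancer samples.
#' @param ff_mat,ffpe_mat,pairing Paired FF/FFPE matrices and their pairing
#'   table (see [paired_concordance_filter()]).
#' @param survival_records Optional survival table (`sample_id`, `time`,
#'   `event`) for the predicted samples.
#' @param stable_fdr,deg_fdr FDR levels of the DEG caller.
#' @param pair_fdr FDR for DEG-anchored opposite pairs.
#' @param min_concordant FF/FFPE concordance requirement.
#' @param cutoffs,min_accuracy Passed to [select_relapse_signature()].
#' @param out_dir Optional output directory.
#' @return List with `degs`, `candidates`, `signature`, `predictions`,
#'   `survival_report` (or `NULL`), `manifest`.
#' @export
run_relapse_pipeline <- function(expression, phenotype,
                                 ff_mat, ffpe_mat, pairing,
                                 survival_records = NULL,
                                 stable_fdr = 0.20, deg_fdr = 0.05,
                                 pair_fdr = 0.01, min_concordant = 10,
                                 cutoffs = c(0.49, 0.50, 0.51),
                                 min_accuracy = 0.80,
                                 out_dir = NULL) {
  manifest <- new_manifest(list(stable_fdr = stable_fdr, deg_fdr = deg_fdr,
                                pair_fdr = pair_fdr,
                                min_concordant = min_concordant,
                                cutoffs = cutoffs, min_accuracy = min_accuracy))
  st <- run_stage(manifest, "inputs", ncol(expression), {
    validate_expression_matrix(expression)
    phenotype <- validate_phenotype_table(phenotype)
    if (is.null(phenotype$stage)) stop("phenotype table has no 'stage' column")
    phenotype
  })
  manifest <- st$manifest; phenotype <- st$result
  is_stage <- function(st_) phenotype$group == "cancer" & !is.na(phenotype$stage) &
    phenotype$stage == st_
  samples_i <- intersect(phenotype$sample_id[is_stage("I")], colnames(expression))
  samples_iv <- intersect(phenotype$sample_id[is_stage("IV")], colnames(expression))
  samples_mid <- intersect(phenotype$sample_id[is_stage("II") | is_stage("III")],
                           colnames(expression))
  if (length(samples_i) == 0 || length(samples_iv) == 0) {
    stop("stage 'inputs' failed: need stage I and stage IV samples", call. = FALSE)
  }

  st <- run_stage(manifest, "rankcomp_degs", length(samples_i) + length(samples_iv),
                  rankcomp_degs(expression, expression, samples_i, samples_iv,
                                stable_fdr = stable_fdr, deg_fdr = deg_fdr))
  manifest <- st$manifest; degs <- st$result

  st <- run_stage(manifest, "anchored_pairs", nrow(degs),
                  deg_anchored_opposite_pairs(expression, expression, degs,
                                              samples_iv = samples_iv,
                                              samples_i = samples_i,
                                              fdr = pair_fdr))
  manifest <- st$manifest; anchored <- st$result
  if (nrow(anchored) == 0) {
    stop("stage 'anchored_pairs' failed: empty candidate list (",
         nrow(degs), " DEGs, 0 significant pairs)", call. = FALSE)
  }

  st <- run_stage(manifest, "concordance_filter", nrow(anchored),
                  paired_concordance_filter(anchored, ff_mat, ffpe_mat, pairing,
                                            min_concordant = min_concordant))
  manifest <- st$manifest; filtered <- st$result
  if (nrow(filtered) == 0) {
    stop("stage 'concordance_filter' failed: no pair concordant in >= ",
         min_concordant, " FF/FFPE pairs (", nrow(anchored), " candidates in)",
         call. = FALSE)
  }

  st <- run_stage(manifest, "coverage_ranking", nrow(filtered), {
    ranked <- coverage_difference(filtered, expression, expression,
                                  samples_iv, samples_i)
    sort_relapse_candidates(ranked)
  })
  manifest <- st$manifest; ranked <- st$result

  blocks <- partition_candidates(ranked)
  manifest$stages[["partition"]] <- list(n_in = nrow(ranked),
                                         n_out = length(blocks),
                                         block_sizes = vapply(blocks, nrow, 0L))

  st <- run_stage(manifest, "selection", length(blocks),
                  select_relapse_signature(blocks, expression, expression,
                                           samples_iv, samples_i,
                                           cutoffs = cutoffs,
                                           min_accuracy = min_accuracy))
  manifest <- st$manifest; signature <- st$result

  st <- run_stage(manifest, "predict", length(samples_mid),
                  predict(signature, expression[, samples_mid, drop = FALSE]))
  manifest <- st$manifest; predictions <- st$result

  survival_report <- NULL
  if (!is.null(survival_records)) {
    st <- run_stage(manifest, "survival", nrow(survival_records), {
      rec <- merge(survival_records,
                   predictions[, c("sample_id", "label")], by = "sample_id")
      rec$risk_group <- rec$label
      if (length(unique(rec$risk_group)) < 2) {
        stop("predictions contain a single risk group")
      }
      fit <- cox_fit(rec)
      list(cox = fit,
           schoenfeld = if (fit$converged && fit$n_events >= 3)
             schoenfeld_test(fit) else NULL,
           logrank = logrank_test(rec[rec$risk_group == "high_risk", ],
                                  rec[rec$risk_group == "low_risk", ]),
           km = lapply(split(rec, rec$risk_group), km_curve))
    })
    manifest <- st$manifest; survival_report <- st$result
  }

  out <- list(degs = degs, candidates = ranked, signature = signature,
              predictions = predictions, survival_report = survival_report,
              manifest = manifest)
  if (!is.null(out_dir)) persist_outputs(out_dir, list(
    relapse_degs.tsv = degs,
    relapse_candidates.tsv = ranked,
    relapse_signature.tsv = signature$pairs,
    relapse_selection_grid.csv = signature$grid,
    relapse_predictions.csv = predictions), manifest, "relapse_manifest.json")
  out
}

persist_outputs <- function(out_dir, tables, manifest, manifest_file) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    sep <- if (grepl("\\.csv$", nm)) "," else "\t"
    utils::write.table(tables[[nm]], file.path(out_dir, nm), sep = sep,
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(out_dir, manifest_file),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
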