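# Orchestration of the three study phases: discovery (feature screening
# + model construction on the training cohort), validation (held-out
# ROC, DeLong comparison, cutoff metrics) and development (survival
# stratification by prediction score).

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with its default: 2-mm
#' isotropic resampling, 25-unit bin width, Coiflet-1 wavelet, 8-voxel
#' crop pad; AUC >= 0.7 and |r| >= 0.7 screening/grouping thresholds at
#' alpha = 0.05; the five algorithms; and the cohort simulation
#' settings. The configuration (with its hash) is serialized into every
#' output for provenance.
#'
#' @param target_spacing isotropic resampling target (mm).
#' @param bin_width quantization bin width.
#' @param basis wavelet basis.
#' @param pad crop margin (voxels).
#' @param auc_threshold,r_threshold,alpha selection thresholds.
#' @param algorithms classifier subset to train.
#' @param seed master seed.
#' @param cohort a [cohortConfig()] for simulation-driven runs.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(target_spacing = 2.0, bin_width = 25,
                           basis = "coif1", pad = 8L,
                           auc_threshold = 0.7, r_threshold = 0.7,
                           alpha = 0.05,
                           algorithms = c("RF", "NB", "RR", "ANN", "SVM"),
                           seed = 1L,
                           cohort = cohortConfig(seed = seed)) {
  stopifnot(target_spacing > 0, bin_width > 0,
            auc_threshold > 0, auc_threshold < 1,
            r_threshold > 0, r_threshold < 1, alpha > 0, alpha < 1,
            all(algorithms %in% c("RF", "NB", "RR", "ANN", "SVM")))
  cfg <- structure(list(target_spacing = target_spacing,
                        bin_width = bin_width, basis = basis,
                        pad = as.integer(pad),
                        auc_threshold = auc_threshold,
                        r_threshold = r_threshold, alpha = alpha,
                        algorithms = algorithms, seed = as.integer(seed),
                        cohort = cohort),
                   class = "PipelineConfig")
  cfg$hash <- .configHash(cfg[setdiff(names(cfg), "hash")])
  cfg
}

#' Simulate a cohort to disk
#'
#' Wraps [generateCohort()] with the config's cohort settings.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir output directory.
#' @param force overwrite non-empty directory.
#' @return invisibly, the cohort bundle.
#' @export
cmdSimulate <- function(config, out_dir, force = FALSE)
  generateCohort(config$cohort, out_dir, force = force)

#' Extract features for a cohort directory
#'
#' @param config a [pipelineConfig()].
#' @param cohort_dir directory with images, masks and `clinical.csv`.
#' @param out_csv optional path for the feature CSV.
#' @return the feature SummarizedExperiment.
#' @export
cmdExtract <- function(config, cohort_dir, out_csv = NULL) {
  se <- extractCohort(cohort_dir,
                      target_spacing = config$target_spacing,
                      bin_width = config$bin_width,
                      basis = config$basis, pad = config$pad)
  S4Vectors::metadata(se)$config_hash <- config$hash
  if (!is.null(out_csv)) writeFeatureCsv(se, out_csv)
  se
}

#' Discovery phase: screen, group, train, training ROC, cutoff
#'
#' On the training cohort only: AUC screening, correlation grouping,
#' training of the configured algorithms on the group representatives,
#' training-cohort ROC per model (RF scored out-of-bag, others by
#' resubstitution, sources flagged), and the Youden cutoff derived from
#' the RF training scores.
#'
#' @param config a [pipelineConfig()].
#' @param se feature SummarizedExperiment (all cases; `cohort` column
#'   in colData marks "training"/"validation").
#' @return list with `screening`, `groups`, `selected`, `models`,
#'   `training_scores`, `training_roc`, `cutoff`.
#' @export
cmdDiscover <- function(config, se) {
  .checkHash(config, se)
  clin <- as.data.frame(SummarizedExperiment::colData(se))
  tr <- clin$cohort == "training"
  if (sum(clin$response[tr]) < 2)
    stop("fewer than 2 responders in the training cohort; models undefined")
  m <- SummarizedExperiment::assay(se, "features")[, tr, drop = FALSE]
  labels <- clin$response[tr]
  screening <- screenFeatures(m, labels,
                              auc_threshold = config$auc_threshold,
                              alpha = config$alpha)
  groups <- correlationGroup(m, screening,
                             r_threshold = config$r_threshold,
                             alpha = config$alpha)
  selected <- selectedFeatures(groups)
  if (!length(selected)) stop("no features survived selection")
  models <- setNames(lapply(seq_along(config$algorithms), function(k)
    trainModel(config$algorithms[k], m, labels, selected,
               seed = as.integer(.subSeed(config$seed, 7000 + k)))),
    config$algorithms)
  training_scores <- do.call(rbind, lapply(names(models), function(a) {
    src <- if (a == "RF") "out_of_bag" else "resubstitution"
    cbind(algorithm = a, scoreCases(models[[a]], m, source = src),
          cohort = "training")
  }))
  training_roc <- lapply(models, function(mod) {
    src <- if (algorithm(mod) == "RF") "out_of_bag" else "resubstitution"
    evaluateRoc(scoreCases(mod, m, source = src)$score, labels)
  })
  rf_scores <- training_scores[training_scores$algorithm == "RF", ]
  cutoff <- youdenCutoff(rf_scores$score, labels)
  list(screening = screening, groups = groups, selected = selected,
       models = models, training_scores = training_scores,
       training_roc = training_roc, cutoff = cutoff,
       config_hash = config$hash)
}

#' Validation phase: held-out ROC, DeLong matrix, cutoff metrics
#'
#' Scores the validation cohort with each trained model, computes
#' held-out AUCs with DeLong CIs, the pairwise DeLong p-value matrix
#' (diagonal p = 1 by convention), and accuracy / sensitivity /
#' specificity of the RF model at the discovery-phase cutoff. Training
#' and validation case ids must be disjoint (leakage guard).
#'
#' @param config a [pipelineConfig()].
#' @param discovery result of [cmdDiscover()].
#' @param se feature SummarizedExperiment.
#' @return list with `scores`, `roc`, `delong`, `cutoff_metrics`.
#' @export
cmdValidate <- function(config, discovery, se) {
  .checkHash(config, se)
  if (!identical(discovery$config_hash, config$hash))
    stop("discovery artifacts come from a different configuration")
  clin <- as.data.frame(SummarizedExperiment::colData(se))
  va <- clin$cohort == "validation"
  tr_ids <- clin$case_id[clin$cohort == "training"]
  va_ids <- clin$case_id[va]
  if (length(intersect(tr_ids, va_ids)))
    stop("training/validation case ids overlap: ",
         paste(intersect(tr_ids, va_ids), collapse = ", "))
  m <- SummarizedExperiment::assay(se, "features")[, va, drop = FALSE]
  labels <- clin$response[va]
  scores <- lapply(discovery$models, function(mod)
    scoreCases(mod, m, source = "held_out"))
  roc <- lapply(scores, function(s) evaluateRoc(s$score, labels))
  algs <- names(discovery$models)
  delong <- matrix(1, length(algs), length(algs),
                   dimnames = list(algs, algs))
  if (length(algs) > 1)
    for (i in seq_along(algs)[-length(algs)])
      for (j in (i + 1):length(algs)) {
        p <- delongCompare(scores[[i]]$score, scores[[j]]$score,
                           labels)$p_value
        delong[i, j] <- delong[j, i] <- p
      }
  cm <- cutoffMetrics(scores[["RF"]]$score, labels,
                      discovery$cutoff$threshold)
  list(scores = scores, roc = roc, delong = delong, cutoff_metrics = cm)
}

#' Development phase: survival stratification by prediction score
#'
#' Runs [runPrognosis()] twice, as the study design does: on the
#' validation cohort alone and on all cases. Training-cohort cases are
#' stratified by their out-of-bag RF scores, validation cases by their
#' held-out scores.
#'
#' @param config a [pipelineConfig()].
#' @param discovery result of [cmdDiscover()].
#' @param validation result of [cmdValidate()].
#' @param se feature SummarizedExperiment.
#' @return list with `validation_only` and `all_cases` reports plus the
#'   score table used.
#' @export
cmdPrognosis <- function(config, discovery, validation, se) {
  clin <- as.data.frame(SummarizedExperiment::colData(se))
  rf_tr <- discovery$training_scores
  rf_tr <- rf_tr[rf_tr$algorithm == "RF", c("case_id", "score")]
  rf_va <- validation$scores[["RF"]][, c("case_id", "score")]
  scores <- rbind(rf_tr, rf_va)
  thr <- discovery$cutoff$threshold
  va_clin <- clin[clin$cohort == "validation", ]
  list(validation_only = runPrognosis(rf_va, thr, va_clin),
       all_cases = runPrognosis(scores, thr, clin),
       scores = scores, threshold = thr)
}

#' Run the full pipeline end to end
#'
#' simulate (optional) -> extract -> discover -> validate -> prognosis.
#'
#' @param config a [pipelineConfig()].
#' @param work_dir working directory for the cohort and artifacts.
#' @param simulate generate a synthetic cohort first (default TRUE; set
#'   FALSE if `work_dir` already holds a cohort).
#' @param force passed to [cmdSimulate()].
#' @param verbose log progress.
#' @return list with `se`, `discovery`, `validation`, `prognosis`.
#' @export
runPipeline <- function(config, work_dir, simulate = TRUE, force = FALSE,
                        verbose = FALSE) {
  cohort_dir <- file.path(work_dir, "cohort")
  if (simulate) cmdSimulate(config, cohort_dir, force = force)
  se <- cmdExtract(config, cohort_dir)
  discovery <- cmdDiscover(config, se)
  validation <- cmdValidate(config, discovery, se)
  prognosis <- cmdPrognosis(config, discovery, validation, se)
  list(se = se, discovery = discovery, validation = validation,
       prognosis = prognosis, config = config)
}

.checkHash <- function(config, se) {
  h <- S4Vectors::metadata(se)$config_hash
  if (!is.null(h) && !identical(h, config$hash))
    stop("feature table was extracted under a different configuration ",
         "(hash mismatch)")
}
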