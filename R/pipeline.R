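#' Default run configuration
#'
#' A single nested configuration holding every constant of the workflow —
#' the genome model, simulation group sizes, the PFE constants (prior
#' weight 20, 2000 draws, 5 controls of 20 genes, Gamma(0.5, 1) margin),
#' the model search (candidates per family, K = 10, 5 folds) and the
#' evaluation settings (target sensitivity 0.95, prevalence grid). The
#' configuration is YAML-serializable and echoed into every run directory.
#'
#' @param seed global seed from which all stage seeds are derived.
#' @return Nested list of class `RunConfig`.
#' @export
defaultRunConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    version = as.character(utils::packageVersion("cfFragSig")),
    genome = list(n_arms = 39, arm_length = 1e5, bin_width = 1e4,
                  n_target_genes = 40, background_size = 330),
    simulate = list(
      train = list(n_cancer = 40, n_benign = 10, n_healthy = 30),
      validation = list(n_cancer = 20, n_benign = 5, n_healthy = 15),
      tumor_fraction = NULL,
      target_fragment_count = 117000L,
      stage_tf = c(I = 0.02, II = 0.05, III = 0.12)),
    pfe = list(prior_weight = 20, n_dirichlet = 2000, n_controls = 5,
               genes_per_control = 20, gamma_shape = 0.5, gamma_rate = 1),
    model = list(n_candidates = 30, K = 10, folds = 5),
    evaluation = list(target_sensitivity = 0.95,
                      prevalences = c(0.001, 0.01, 0.1, 0.2, 0.5),
                      n_calibration_bins = 10)),
    class = "RunConfig")
}

#' Read / write a run configuration as YAML
#' @param config a `RunConfig` list.
#' @param path YAML path.
#' @return The configuration (read) or `path` (write).
#' @export
writeRunConfig <- function(config, path) {
  write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  structure(read_yaml(path), class = "RunConfig")
}

#' Extract the three feature matrices for a cohort
#'
#' @param fragsets named list of [FragmentSet-class] objects.
#' @param model a [GenomeModel-class].
#' @param baseline healthy CNV baseline from [buildBaseline()].
#' @param pfe_config a [pfeConfig()].
#' @return Named list of matrices `CNV`, `FSD`, `PFE` (samples in rows).
#' @export
extractFeatureMatrices <- function(fragsets, model, baseline,
                                   pfe_config = pfeConfig()) {
  list(CNV = cnvFeatureMatrix(fragsets, model, baseline),
       FSD = fsdFeatureMatrix(fragsets, model),
       PFE = pfeMatrix(fragsets, model, pfe_config))
}

#' Run the end-to-end workflow
#'
#' simulate -> features -> train -> predict -> evaluate on a synthetic
#' cohort pair. Training and validation cohorts are simulated with
#' disjoint ids; the CNV baseline comes from training healthy samples
#' only; the ensemble is fitted strictly on training matrices; validation
#' samples are scored through the frozen model and cutoff. If
#' `config$simulate$validation` is `NULL`, train-only outputs are produced
#' and evaluation of a validation cohort is skipped with a warning.
#'
#' @param config a `RunConfig`, see [defaultRunConfig()].
#' @param out_dir optional run directory; when given, feature matrices,
#'   the model manifest, risk scores and reports are written there along
#'   with a YAML echo of the configuration.
#' @return List with the model, per-cohort scores and reports.
#' @export
runPipeline <- function(config = defaultRunConfig(), out_dir = NULL) {
  seed <- config$seed
  g <- config$genome
  model <- buildGenomeModel(n_arms = g$n_arms, arm_length = g$arm_length,
                            bin_width = g$bin_width,
                            n_target_genes = g$n_target_genes,
                            background_size = g$background_size,
                            seed = deriveSeed(seed, 11L))
  sim <- config$simulate
  simGroup <- function(gcfg, cohort, mseed)
    simulateCohort(model,
                   n_cancer = gcfg$n_cancer, n_benign = gcfg$n_benign,
                   n_healthy = gcfg$n_healthy, cohort = cohort,
                   tumor_fraction = sim$tumor_fraction,
                   stage_tf = unlist(sim$stage_tf),
                   target_fragment_count = sim$target_fragment_count,
                   master_seed = mseed)
  train <- simGroup(sim$train, "train", deriveSeed(seed, 21L))
  val <- if (!is.null(sim$validation))
    simGroup(sim$validation, "validation", deriveSeed(seed, 22L)) else NULL
  if (!is.null(val) &&
      length(intersect(train$sheet$sample_id, val$sheet$sample_id)))
    stopf("training and validation sample sheets overlap")

  healthy <- train$samples[train$sheet$label == "healthy"]
  baseline <- buildBaseline(healthy, model)
  pcfg <- pfeConfig(prior_weight = config$pfe$prior_weight,
                    n_dirichlet = config$pfe$n_dirichlet,
                    n_controls = config$pfe$n_controls,
                    genes_per_control = config$pfe$genes_per_control,
                    gamma_shape = config$pfe$gamma_shape,
                    gamma_rate = config$pfe$gamma_rate,
                    seed = deriveSeed(seed, 31L))
  Xtrain <- extractFeatureMatrices(train$samples, model, baseline, pcfg)
  yTrain <- as.integer(train$sheet$label == "cancer")

  ens <- fitEnsemble(Xtrain, yTrain,
                     n_candidates = config$model$n_candidates,
                     K = config$model$K, folds = config$model$folds,
                     seed = deriveSeed(seed, 41L),
                     target_sensitivity =
                       config$evaluation$target_sensitivity)

  oof <- trainingScores(ens)
  trainReport <- confusionMetrics(unname(oof), yTrain,
                                  ensembleCutoff(ens), "training(OOF)")
  trainCal <- calibrationReport(unname(oof), yTrain,
                                config$evaluation$n_calibration_bins)
  reports <- list(training = trainReport, training_calibration = trainCal)
  valScores <- NULL
  if (is.null(val)) {
    warning("no validation cohort configured; evaluation skipped",
            call. = FALSE)
  } else {
    Xval <- extractFeatureMatrices(val$samples, model, baseline, pcfg)
    valScores <- predictRisk(ens, Xval)
    yVal <- as.integer(val$sheet$label == "cancer")
    valAUC <- rocAUC(valScores$risk, yVal)
    valReport <- confusionMetrics(valScores$risk, yVal,
                                  ensembleCutoff(ens), "validation")
    reports$validation <- valReport
    reports$validation_auc <- valAUC[c("auc", "ci")]
    reports$validation_calibration <-
      calibrationReport(valScores$risk, yVal,
                        config$evaluation$n_calibration_bins)
    reports$prevalence <- prevalenceAdjusted(
      valReport$sensitivity$est, valReport$specificity$est,
      config$evaluation$prevalences)
  }

  out <- list(config = config, model = model, baseline = baseline,
              ensemble = ens,
              training = list(sheet = train$sheet,
                              oof_scores = oof),
              validation = if (is.null(val)) NULL else
                list(sheet = val$sheet, scores = valScores),
              reports = reports)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeRunConfig(config, file.path(out_dir, "config.yaml"))
    writeBaseline(baseline, file.path(out_dir, "cnv_baseline.tsv"))
    fwrite(ensembleManifest(ens), file.path(out_dir, "manifest.tsv"),
           sep = "\t")
    fwrite(data.table(sample_id = names(oof), oof_risk = unname(oof)),
           file.path(out_dir, "training_oof_scores.tsv"), sep = "\t")
    if (!is.null(valScores))
      fwrite(valScores, file.path(out_dir, "validation_scores.tsv"),
             sep = "\t")
    summary <- list(cutoff = ensembleCutoff(ens),
                    training_counts = as.list(trainReport$counts))
    if (!is.null(val))
      summary$validation_auc <- reports$validation_auc$auc
    write_json(summary, file.path(out_dir, "summary.json"),
               auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
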