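# One-call orchestration of the full benchmark: synthesize -> aggregate ->
# encode -> split -> select (up to six methods) -> reconstruction evaluation
# -> outcome case study -> comparison report.

.BENCH_METHODS <- c("ls", "mcfs", "aefs", "pfa", "cae", "caeww")

#' Default demonstration benchmark configuration
#'
#' A desk-scale configuration exercising all six selector variants on
#' synthetic data: a modest cohort, a three-level code tree, and reduced
#' autoencoder budgets so the full pipeline runs in minutes on one CPU.
#'
#' @param seed master seed; all stage seeds derive from it by name.
#' @return a nested configuration list.
#' @export
demoBenchmarkConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    methods = .BENCH_METHODS,
    n_best = 12L,
    window_days = 90L,
    train_fraction = 0.67,
    synth = list(n_patients = 150L, records_per_patient = 6,
                 hierarchy_shape = c(4L, 3L, 3L), n_latent = 5L,
                 factor_activation_prob = 0.35, emission_prob = 0.9,
                 redundancy_rate = 0.5, outcome_codes = 3L,
                 outcome_weight = 2, outcome_prevalence = 0.08,
                 noise_flip = 0.02, span_days = 360L),
    cae = list(epochs = 60L, batch_size = 64L, learning_rate = 1e-3,
               decoder_hidden = c(64L, 64L)),
    aefs = list(epochs = 60L, alpha = 0.001, beta = 0.1),
    reconstruction = list(epochs = 40L),
    case_study = list(cv_folds = 3L,
                      grid = expand.grid(max_depth = c(3L, 5L),
                                         eta = c(0.1, 0.3),
                                         nrounds = 100L,
                                         min_child_weight = 1))
  )
}

#' Read a benchmark configuration from YAML
#'
#' Unspecified fields fall back to [demoBenchmarkConfig()] values.
#'
#' @param path YAML file.
#' @return a configuration list.
#' @export
readBenchmarkConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- demoBenchmarkConfig(seed = user$seed %||% 1L)
  utils::modifyList(cfg, user)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.logStage <- function(stage, seed, t0) {
  message(sprintf("[codesieve] stage=%s seed=%d elapsed=%.1fs",
                  stage, seed, as.numeric(Sys.time()) - t0))
}

#' Run the full feature-selection benchmark
#'
#' Executes every stage in order under a single master seed (per-stage seeds
#' derive deterministically from the stage name), and returns one comparison
#' report ranking the requested methods on reconstruction accuracy and BCE,
#' outcome AUC, mean absolute Shapley value and mean selected code depth.
#' The reference for DeLong/McNemar and depth comparisons is the
#' weight-adjusted CAE when it is among the methods, otherwise the first
#' method.
#'
#' @param config a configuration list ([demoBenchmarkConfig()] or
#'   [readBenchmarkConfig()]).
#' @param outDir optional directory; when given, the report, per-method
#'   selections, matrices and a run manifest are written there.
#' @return list with `report` (data frame, one row per method),
#'   `selections`, `truth` and `manifest`.
#' @export
runBenchmark <- function(config = demoBenchmarkConfig(), outDir = NULL) {
  t0 <- as.numeric(Sys.time())
  master <- as.integer(config$seed %||% 1L)
  seeds <- vapply(c("synth", "split", "select", "evaluate", "case_study"),
                  function(s) .deriveSeed(master, s), integer(1))
  sc <- config$synth
  scfg <- synthConfig(
    nPatients = sc$n_patients, recordsPerPatient = sc$records_per_patient,
    hierarchyShape = sc$hierarchy_shape, nLatent = sc$n_latent,
    factorActivationProb = sc$factor_activation_prob,
    emissionProb = sc$emission_prob, redundancyRate = sc$redundancy_rate,
    outcomeCodes = sc$outcome_codes, outcomeWeight = sc$outcome_weight,
    outcomePrevalence = sc$outcome_prevalence, noiseFlip = sc$noise_flip,
    spanDays = sc$span_days, seed = seeds[["synth"]])
  sim <- generateRecords(scfg)
  .logStage("synth", seeds[["synth"]], t0)
  agg <- aggregateRecords(sim$records, config$window_days)
  rm_all <- encodeOneHot(agg, sim$truth$hierarchy)
  rm_all <- generateOutcome(rm_all, sim$truth, scfg, seed = seeds[["synth"]])
  split <- splitByPatient(rm_all, config$train_fraction, seeds[["split"]])
  .logStage("encode_split", seeds[["split"]], t0)
  train <- split$train
  test <- split$test
  nBest <- min(config$n_best, nrow(rm_all))
  methodsWanted <- intersect(config$methods, .BENCH_METHODS)
  selections <- list()
  for (m in methodsWanted) {
    s <- seeds[["select"]]
    selections[[m]] <- switch(m,
      ls = laplacianScore(train, nBest = nBest),
      mcfs = mcfsScores(train, nBest = nBest,
                        nEigvecs = min(5L, ncol(train) - 2L)),
      aefs = aefsSelect(train, nBest = nBest,
                        alpha = config$aefs$alpha, beta = config$aefs$beta,
                        epochs = config$aefs$epochs, seed = s),
      pfa = pfaSelect(train, nBest = nBest, seed = s),
      cae = caeSelect(train, nBest = nBest, epochs = config$cae$epochs,
                      batchSize = config$cae$batch_size,
                      learningRate = config$cae$learning_rate,
                      decoderHidden = config$cae$decoder_hidden, seed = s),
      caeww = caeSelect(train, nBest = nBest, epochs = config$cae$epochs,
                        batchSize = config$cae$batch_size,
                        learningRate = config$cae$learning_rate,
                        decoderHidden = config$cae$decoder_hidden,
                        featureWeights = caeFeatureWeights(train),
                        seed = s))
    .logStage(paste0("select_", m), s, t0)
  }
  reference <- if ("caeww" %in% names(selections)) "caeww"
               else names(selections)[1L]
  rows <- list()
  shap <- list()
  for (m in names(selections)) {
    recon <- evaluateReconstruction(train, test, selections[[m]],
                                    seed = seeds[["evaluate"]],
                                    epochs = config$reconstruction$epochs)
    cs <- caseStudy(train, test, selections[[m]],
                    referenceSelection = if (m == reference) NULL
                                         else selections[[reference]],
                    seed = seeds[["case_study"]],
                    cvFolds = config$case_study$cv_folds,
                    grid = config$case_study$grid)
    shap[[m]] <- cs@shapMeanAbs
    rows[[m]] <- data.frame(
      method = m,
      n_selected = length(selections[[m]]@selected),
      mean_accuracy = recon@meanAccuracy,
      baseline_mean_accuracy = recon@baselineMeanAccuracy,
      mean_bce = recon@meanBce,
      baseline_mean_bce = recon@baselineMeanBce,
      accuracy_t_p = recon@tTestP,
      outcome_accuracy = cs@accuracy,
      outcome_f1 = cs@f1,
      outcome_auc = cs@aucRoc,
      delong_p_vs_reference = cs@delongP,
      mcnemar_p_vs_reference = cs@mcnemarP,
      mean_abs_shapley = mean(cs@shapMeanAbs),
      mean_selected_depth = cs@meanSelectedDepth)
    .logStage(paste0("evaluate_", m), seeds[["evaluate"]], t0)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  depthTab <- if (length(selections) >= 2L) {
    depthImportanceComparison(selections, codeHierarchy(rm_all),
                              shap = shap, reference = reference)
  } else {
    NULL
  }
  manifest <- list(master_seed = master, stage_seeds = as.list(seeds),
                   methods = names(selections), n_best = nBest,
                   n_records = ncol(rm_all), n_features = nrow(rm_all),
                   outcome_prevalence =
                     S4Vectors::metadata(rm_all)$outcome_prevalence,
                   version = as.character(
                     utils::packageVersion("CodeSieve")),
                   artifacts = character(0),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  out <- list(report = report, depth_comparison = depthTab,
              selections = selections, truth = sim$truth,
              manifest = manifest)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.csv(report, file.path(outDir, "report.csv"),
                     row.names = FALSE)
    if (!is.null(depthTab))
      utils::write.csv(depthTab, file.path(outDir, "depth_comparison.csv"),
                       row.names = FALSE)
    for (m in names(selections))
      writeSelection(selections[[m]],
                     file.path(outDir, paste0("selection_", m, ".json")))
    writeRecordMatrix(rm_all, file.path(outDir, "matrix"))
    manifest$artifacts <- list.files(outDir, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$manifest <- manifest
  }
  out
}
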