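## End-to-end pipeline: simulate (or load) -> denoise -> epoch -> features
## -> stratified split -> DBN train -> predict -> report.

#' Default end-to-end pipeline configuration
#'
#' The simulated study design: 28 subjects, the five default condition
#' profiles, 60 s recordings at 256 Hz on 4 channels, clean by default
#' (denoising switches on automatically when artifact amplitudes are
#' non-zero), 4 s non-overlapping epochs, standard feature settings, a
#' 50-40-30 DBN with a 5-way softmax head and 500 fine-tune iterations,
#' and a stratified 72/28 train/test split.
#'
#' @param seed master seed for the whole run.
#' @return a nested named list; edit fields and pass to [runPipeline()].
#' @export
defaultPipelineConfig <- function(seed = 7L) {
  list(
    seed = as.integer(seed),
    cohort = list(nSubjects = 28L, durationS = 60, fs = 256, nChannels = 4L),
    artifacts = list(blinkRate = 0, blinkAmplitude = 0,
                     lineFreq = 50, lineAmplitude = 0),
    denoise = "auto",                 # TRUE / FALSE / "auto"
    epoch = list(epochS = 4, overlap = 0),
    features = list(m = 2, r = 0.2, nEntropyWindows = 25L, nFberWindows = 5L),
    dbn = list(layerSizes = c(50L, 40L, 30L), cdK = 1L, lrPretrain = 0.01,
               epochsPretrain = 30L, lrFinetune = 0.1,
               iterationsFinetune = 500L, batchSize = 64L),
    split = list(trainFraction = 0.72)
  )
}

## Stratified split: within every subject x condition cell, a seeded draw
## of round(trainFraction * n) rows goes to training.
stratifiedSplit <- function(labels, subjects, trainFraction, seed) {
  idx <- seq_along(labels)
  cells <- split(idx, paste(subjects, labels, sep = "/"))
  train <- integer()
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    nTrain <- max(1L, round(trainFraction * length(cell)))
    nTrain <- min(nTrain, length(cell))
    pick <- withLocalSeed(childSeed(seed, 30000L + ci),
                          sample(cell, nTrain))
    train <- c(train, pick)
  }
  sort(train)
}

#' Run the full classification pipeline
#'
#' Generates (or loads) the cohort, optionally denoises, cuts epochs,
#' builds the feature matrix, splits it stratified by condition within
#' subject, trains the DBN, predicts the held-out rows and assembles a
#' [ClassificationReport-class]. Fully deterministic given `config$seed`.
#'
#' @param config a config list as from [defaultPipelineConfig()], or the
#'   path of a YAML file holding one.
#' @param outDir optional directory; when given, the feature matrix, the
#'   trained model, per-epoch predictions, the confusion matrices (counts
#'   and percent), per-subject accuracies, the MSE trace and a summary are
#'   written there as CSV / structured text.
#' @param recordings optional list of [EEGRecording-class] objects to use
#'   instead of simulating a cohort.
#' @return a [ClassificationReport-class].
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = NULL,
                        recordings = NULL) {
  if (is.character(config)) config <- read_yaml(config)
  def <- defaultPipelineConfig()
  for (k in names(def)) if (is.null(config[[k]])) config[[k]] <- def[[k]]
  seed <- config$seed
  if (is.null(seed)) stop("config$seed is required", call. = FALSE)

  art <- do.call(artifactSpec, config$artifacts)
  message("stage: simulate")
  if (is.null(recordings)) {
    recordings <- generateCohort(
      config$cohort$nSubjects, defaultProfiles(),
      durationS = config$cohort$durationS, fs = config$cohort$fs,
      nChannels = config$cohort$nChannels, artifacts = art, seed = seed)
  }

  doDenoise <- if (identical(config$denoise, "auto"))
    (art@blinkAmplitude > 0 || art@lineAmplitude > 0)
  else isTRUE(config$denoise)
  if (doDenoise) {
    message("stage: denoise")
    recordings <- lapply(seq_along(recordings), function(i)
      denoiseRecording(recordings[[i]], lineFreq = art@lineFreq,
                       seed = childSeed(seed, 40000L + i)))
  }

  message("stage: epoch")
  epochs <- segmentEpochs(recordings, epochS = config$epoch$epochS,
                          overlap = config$epoch$overlap)

  message("stage: features")
  fm <- buildFeatureMatrix(epochs, m = config$features$m,
                           r = config$features$r,
                           nEntropyWindows = config$features$nEntropyWindows,
                           nFberWindows = config$features$nFberWindows)

  trainIdx <- stratifiedSplit(fm@y, fm@subjectIds,
                              config$split$trainFraction, seed)
  testIdx <- setdiff(seq_along(fm@y), trainIdx)

  message("stage: train")
  cfg <- trainConfig(layerSizes = config$dbn$layerSizes,
                     cdK = config$dbn$cdK,
                     lrPretrain = config$dbn$lrPretrain,
                     epochsPretrain = config$dbn$epochsPretrain,
                     lrFinetune = config$dbn$lrFinetune,
                     iterationsFinetune = config$dbn$iterationsFinetune,
                     batchSize = config$dbn$batchSize, seed = seed)
  fit <- trainDBN(fm, cfg, trainIdx)

  message("stage: predict")
  pred <- predictDBN(fit$model, fm@X[testIdx, , drop = FALSE])

  message("stage: report")
  yTest <- fm@y[testIdx]
  subjTest <- fm@subjectIds[testIdx]
  nClasses <- max(5L, length(unique(fm@y)))
  acc <- perSubjectAccuracy(yTest, pred$labels, subjTest)
  report <- new("ClassificationReport",
                confusionPct = confusionMatrix(yTest, pred$labels, nClasses),
                confusionCounts = confusionMatrix(yTest, pred$labels,
                                                  nClasses, percent = FALSE),
                perSubjectAccuracy = acc$perSubject,
                summary = acc$summary,
                testAccuracy = mean(yTest == pred$labels) * 100,
                mseTrace = fit$trace$msePerIteration)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeFeatureMatrix(fm, file.path(outDir, "features"), trainIdx)
    writeDBNModel(fit$model, file.path(outDir, "model.txt"))
    utils::write.csv(data.frame(row = testIdx, true = yTest,
                                predicted = pred$labels,
                                round(pred$probabilities, 10)),
                     file.path(outDir, "predictions.csv"), row.names = FALSE)
    utils::write.csv(round(report@confusionPct, 4),
                     file.path(outDir, "confusion_pct.csv"))
    utils::write.csv(report@confusionCounts,
                     file.path(outDir, "confusion_counts.csv"))
    utils::write.csv(data.frame(subject = names(acc$perSubject),
                                accuracy = round(acc$perSubject, 4)),
                     file.path(outDir, "per_subject_accuracy.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(iteration = seq_along(report@mseTrace),
                                mse = report@mseTrace),
                     file.path(outDir, "mse_trace.csv"), row.names = FALSE)
    write_yaml(list(testAccuracy = report@testAccuracy,
                    subjectAccuracy = as.list(round(acc$summary, 4)),
                    nEpochs = nrow(fm@X), nTrain = length(trainIdx),
                    nTest = length(testIdx), seed = seed),
               file.path(outDir, "summary.yaml"))
  }
  report
}
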