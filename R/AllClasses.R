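#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ConditionProfile: spectral signature of one listening condition
#'
#' Describes how one experimental condition (no music, or one of four music
#' styles) shapes the simulated EEG: the relative power of each rhythm band
#' and a regularity scalar that mixes deterministic oscillation against
#' band-limited noise (higher regularity means lower sample entropy).
#'
#' @slot conditionId integer in 0-4.
#' @slot bandPower named numeric over the five rhythms; non-negative
#'   relative weights, not all zero.
#' @slot regularity scalar in [0, 1].
#' @export
setClass("ConditionProfile",
  representation(conditionId = "integer", bandPower = "numeric",
                 regularity = "numeric"))

setValidity("ConditionProfile", function(object) {
  msg <- character()
  if (length(object@conditionId) != 1L ||
      object@conditionId < 0L || object@conditionId > 4L)
    msg <- c(msg, "conditionId must be a single integer in 0-4")
  if (!identical(sort(names(object@bandPower)), sort(rhythmNames())))
    msg <- c(msg, "bandPower must be named over exactly the five rhythms")
  if (any(object@bandPower < 0) || all(object@bandPower == 0))
    msg <- c(msg, "bandPower weights must be >= 0 and not all zero")
  if (length(object@regularity) != 1L || object@regularity < 0 ||
      object@regularity > 1)
    msg <- c(msg, "regularity must be a scalar in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a ConditionProfile
#'
#' @param conditionId integer 0-4 (0 is conventionally the no-music condition).
#' @param bandPower named numeric of non-negative relative rhythm powers;
#'   names must be delta, theta, alpha, beta, gamma (any order).
#' @param regularity scalar in [0, 1]; fraction of each band's power carried
#'   by a phase-jittered sinusoid rather than band-limited noise.
#' @return a [ConditionProfile-class] object.
#' @examples
#' conditionProfile(2L, c(delta = .1, theta = .1, alpha = .6,
#'                        beta = .1, gamma = .1), regularity = 0.5)
#' @export
conditionProfile <- function(conditionId, bandPower, regularity = 0.5) {
  unknown <- setdiff(names(bandPower), rhythmNames())
  if (length(unknown))
    stop("unknown rhythm band name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  new("ConditionProfile", conditionId = as.integer(conditionId),
      bandPower = bandPower[rhythmNames()], regularity = as.numeric(regularity))
}

#' ArtifactSpec: artifact contamination parameters
#'
#' @slot blinkRate ocular blink events per minute.
#' @slot blinkAmplitude blink peak amplitude, microvolts.
#' @slot lineFreq mains interference frequency, Hz.
#' @slot lineAmplitude mains sinusoid amplitude, microvolts.
#' @export
setClass("ArtifactSpec",
  representation(blinkRate = "numeric", blinkAmplitude = "numeric",
                 lineFreq = "numeric", lineAmplitude = "numeric"))

setValidity("ArtifactSpec", function(object) {
  v <- c(object@blinkRate, object@blinkAmplitude, object@lineFreq,
         object@lineAmplitude)
  if (any(!is.finite(v)) || any(v < 0))
    "all rates and amplitudes must be finite and >= 0" else TRUE
})

#' Construct an ArtifactSpec
#'
#' @param blinkRate blink events per minute (Poisson rate).
#' @param blinkAmplitude blink peak amplitude in microvolts.
#' @param lineFreq mains frequency in Hz (50 in most of the world).
#' @param lineAmplitude mains sinusoid amplitude in microvolts.
#' @return an [ArtifactSpec-class] object.
#' @examples
#' artifactSpec()                        # defaults: 12/min blinks, 50 Hz mains
#' artifactSpec(blinkRate = 0, lineAmplitude = 0)   # clean
#' @export
artifactSpec <- function(blinkRate = 12, blinkAmplitude = 100,
                         lineFreq = 50, lineAmplitude = 10) {
  new("ArtifactSpec", blinkRate = blinkRate, blinkAmplitude = blinkAmplitude,
      lineFreq = lineFreq, lineAmplitude = lineAmplitude)
}

#' EEGRecording: one multi-channel EEG recording
#'
#' @slot data channels x samples numeric matrix, microvolts.
#' @slot fs sampling rate, Hz.
#' @slot channelLabels character vector, one per channel.
#' @slot subjectId single string.
#' @slot conditionId integer 0-4.
#' @export
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric", channelLabels = "character",
                 subjectId = "character", conditionId = "integer"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data) || !all(is.finite(object@data)))
    msg <- c(msg, "data must be a finite numeric matrix")
  if (ncol(object@data) < object@fs)
    msg <- c(msg, "recording must be at least 1 s long (n_samples >= fs)")
  if (length(object@channelLabels) != nrow(object@data))
    msg <- c(msg, "one channel label per row of data")
  if (object@fs <= 2 * maxBandEdge())
    msg <- c(msg, sprintf("fs must exceed 2 x %g Hz (highest rhythm edge)",
                          maxBandEdge()))
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channelLabels optional channel names (default "ch1", "ch2", ...).
#' @param subjectId subject identifier string.
#' @param conditionId condition label, integer 0-4.
#' @return an [EEGRecording-class] object.
#' @export
eegRecording <- function(data, fs, channelLabels = NULL,
                         subjectId = "S1", conditionId = 0L) {
  data <- as.matrix(data)
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(data)))
  new("EEGRecording", data = data, fs = as.numeric(fs),
      channelLabels = as.character(channelLabels),
      subjectId = as.character(subjectId), conditionId = as.integer(conditionId))
}

#' EpochSet: fixed-length labelled epochs
#'
#' @slot epochs numeric array [n_epochs x n_channels x epoch_samples].
#' @slot labels integer vector of condition ids (0-4), one per epoch.
#' @slot subjectIds character vector, one per epoch.
#' @slot fs sampling rate, Hz.
#' @export
setClass("EpochSet",
  representation(epochs = "array", labels = "integer",
                 subjectIds = "character", fs = "numeric"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L)
    msg <- c(msg, "epochs must be a 3-d array [epoch x channel x sample]")
  else {
    if (length(object@labels) != d[1])
      msg <- c(msg, "one label per epoch")
    if (length(object@subjectIds) != d[1])
      msg <- c(msg, "one subject id per epoch")
  }
  if (length(object@labels) && (min(object@labels) < 0L ||
                                max(object@labels) > 4L))
    msg <- c(msg, "labels must lie in 0-4")
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: epoch-level feature rows
#'
#' Rows are epochs; the first 25 columns are sliding-average sample-entropy
#' values and the last 25 are windowed frequency band energy ratio (FBER)
#' percentages.
#'
#' @slot X numeric matrix [n_epochs x 50].
#' @slot y integer labels, one per row.
#' @slot subjectIds character, one per row.
#' @slot columnNames character(50).
#' @export
setClass("FeatureMatrix",
  representation(X = "matrix", y = "integer", subjectIds = "character",
                 columnNames = "character"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@X))) msg <- c(msg, "X must be finite")
  if (nrow(object@X) != length(object@y)) msg <- c(msg, "one label per row")
  if (nrow(object@X) != length(object@subjectIds))
    msg <- c(msg, "one subject id per row")
  if (ncol(object@X) != length(object@columnNames))
    msg <- c(msg, "one column name per column")
  if (length(msg)) msg else TRUE
})

#' RBMParams: one restricted Boltzmann machine layer
#'
#' @slot W weights [n_hidden x n_visible].
#' @slot bVisible visible biases.
#' @slot bHidden hidden biases.
#' @slot unitType "gaussian" or "bernoulli" visible units.
#' @export
setClass("RBMParams",
  representation(W = "matrix", bVisible = "numeric", bHidden = "numeric",
                 unitType = "character"))

setValidity("RBMParams", function(object) {
  msg <- character()
  if (!all(is.finite(object@W)) || !all(is.finite(object@bVisible)) ||
      !all(is.finite(object@bHidden)))
    msg <- c(msg, "parameters must be finite")
  if (length(object@bHidden) != nrow(object@W))
    msg <- c(msg, "bHidden length must equal nrow(W)")
  if (length(object@bVisible) != ncol(object@W))
    msg <- c(msg, "bVisible length must equal ncol(W)")
  if (!object@unitType %in% c("gaussian", "bernoulli"))
    msg <- c(msg, "unitType must be 'gaussian' or 'bernoulli'")
  if (length(msg)) msg else TRUE
})

#' DBNModel: stacked RBMs plus a softmax head
#'
#' @slot rbms list of [RBMParams-class], input layer first.
#' @slot theta softmax parameters [k_classes x (top_dim + 1)]; the last
#'   column is the bias.
#' @slot classLabels integer class labels, in softmax row order.
#' @slot center,scale standardization statistics fitted on training rows
#'   (empty until the model is trained through [trainDBN]).
#' @export
setClass("DBNModel",
  representation(rbms = "list", theta = "matrix", classLabels = "integer",
                 center = "numericOrNULL", scale = "numericOrNULL"))

setValidity("DBNModel", function(object) {
  msg <- character()
  if (length(object@classLabels) < 2L) msg <- c(msg, "need >= 2 classes")
  if (nrow(object@theta) != length(object@classLabels))
    msg <- c(msg, "theta must have one row per class")
  dims <- vapply(object@rbms, function(r) nrow(r@W), 0L)
  if (length(object@rbms)) {
    for (i in seq_len(length(object@rbms) - 1L))
      if (ncol(object@rbms[[i + 1L]]@W) != nrow(object@rbms[[i]]@W))
        msg <- c(msg, "adjacent RBM layer dimensions must chain")
    top <- nrow(object@rbms[[length(object@rbms)]]@W)
    if (ncol(object@theta) != top + 1L)
      msg <- c(msg, "theta must have top_dim + 1 columns (bias last)")
  }
  if (length(msg)) msg else TRUE
})

#' ClassificationReport: evaluation artifacts of one pipeline run
#'
#' @slot confusionPct row-normalized confusion matrix in percent
#'   (rows = true condition, columns = predicted).
#' @slot confusionCounts raw count matrix.
#' @slot perSubjectAccuracy named numeric, percent per subject.
#' @slot summary named numeric: mean, min, max subject accuracy (percent).
#' @slot testAccuracy pooled test accuracy, percent.
#' @slot mseTrace training mean squared error per fine-tune iteration.
#' @export
setClass("ClassificationReport",
  representation(confusionPct = "matrix", confusionCounts = "matrix",
                 perSubjectAccuracy = "numeric", summary = "numeric",
                 testAccuracy = "numeric", mseTrace = "numeric"))

setValidity("ClassificationReport", function(object) {
  msg <- character()
  rs <- rowSums(object@confusionPct)
  if (any(abs(rs[rs != 0] - 100) > 0.1))
    msg <- c(msg, "non-empty confusion rows must sum to 100 (+-0.1)")
  acc <- object@perSubjectAccuracy
  if (length(acc) && (min(acc) < 0 || max(acc) > 100))
    msg <- c(msg, "accuracies must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "ConditionProfile", function(object) {
  cat(sprintf("ConditionProfile (condition %d, regularity %.2f)\n",
              object@conditionId, object@regularity))
  w <- object@bandPower / sum(object@bandPower)
  cat("  band power:",
      paste(sprintf("%s=%.2f", names(w), w), collapse = " "), "\n")
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    nrow(object@data), ncol(object@data), object@fs,
    ncol(object@data) / object@fs))
  cat(sprintf("  subject %s, condition %d\n",
              object@subjectId, object@conditionId))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet: %d epoch(s) x %d channel(s) x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  if (d[1]) {
    tab <- table(object@labels)
    cat("  epochs per condition:",
        paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  }
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d epoch(s) x %d feature(s)\n",
              nrow(object@X), ncol(object@X)))
  cat(sprintf("  %d subject(s), %d class(es)\n",
              length(unique(object@subjectIds)), length(unique(object@y))))
})

setMethod("show", "RBMParams", function(object) {
  cat(sprintf("RBMParams: %d visible (%s) -> %d hidden\n",
              ncol(object@W), object@unitType, nrow(object@W)))
})

setMethod("show", "DBNModel", function(object) {
  sizes <- c(if (length(object@rbms)) ncol(object@rbms[[1]]@W) else
               ncol(object@theta) - 1L,
             vapply(object@rbms, function(r) nrow(r@W), 0L))
  cat(sprintf("DBNModel: layers %s -> softmax(%d classes)\n",
              paste(sizes, collapse = "-"), length(object@classLabels)))
  cat(if (length(object@center)) "  standardization: fitted\n"
      else "  standardization: none\n")
})

setMethod("show", "ClassificationReport", function(object) {
  cat("ClassificationReport\n")
  cat(sprintf("  test accuracy: %.2f%%\n", object@testAccuracy))
  cat(sprintf("  subject accuracy mean %.2f / min %.2f / max %.2f %%\n",
              object@summary["mean"], object@summary["min"],
              object@summary["max"]))
  cat("  confusion (%):\n")
  print(round(object@confusionPct, 2))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for museeg S4 containers
#'
#' Small read-only accessors; slots are implementation detail.
#'
#' @param object a museeg S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("recordingData", function(object) standardGeneric("recordingData"))
#' @rdname accessors
#' @export
setMethod("recordingData", "EEGRecording", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("conditionId", function(object) standardGeneric("conditionId"))
#' @rdname accessors
#' @export
setMethod("conditionId", "EEGRecording", function(object) object@conditionId)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "EEGRecording", function(object) object@subjectId)

#' @rdname accessors
#' @export
setGeneric("epochArray", function(object) standardGeneric("epochArray"))
#' @rdname accessors
#' @export
setMethod("epochArray", "EpochSet", function(object) object@epochs)

#' @rdname accessors
#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))
#' @rdname accessors
#' @export
setMethod("epochLabels", "EpochSet", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("epochLabels", "FeatureMatrix", function(object) object@y)

#' @rdname accessors
#' @export
setGeneric("epochSubjects", function(object) standardGeneric("epochSubjects"))
#' @rdname accessors
#' @export
setMethod("epochSubjects", "EpochSet", function(object) object@subjectIds)
#' @rdname accessors
#' @export
setMethod("epochSubjects", "FeatureMatrix",
          function(object) object@subjectIds)

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@X)

#' @rdname accessors
#' @export
setGeneric("confusionPct", function(object) standardGeneric("confusionPct"))
#' @rdname accessors
#' @export
setMethod("confusionPct", "ClassificationReport",
          function(object) object@confusionPct)

#' @rdname accessors
#' @export
setGeneric("mseTrace", function(object) standardGeneric("mseTrace"))
#' @rdname accessors
#' @export
setMethod("mseTrace", "ClassificationReport", function(object) object@mseTrace)

#' @rdname accessors
#' @export
setGeneric("subjectAccuracy",
           function(object) standardGeneric("subjectAccuracy"))
#' @rdname accessors
#' @export
setMethod("subjectAccuracy", "ClassificationReport",
          function(object) object@perSubjectAccuracy)
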