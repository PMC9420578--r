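## Denoising pipeline (EMD frequency screening, then FastICA artifact
## rejection) and epoch segmentation.

#' Denoise a recording by FastICA rejection plus EMD screening
#'
#' Two stages. (1) [fastica()] is run across channels, artifact components
#' are flagged by [flagArtifactComponents()], zeroed, and the data
#' back-projected; this stage runs first because spatially coherent
#' artifacts (blinks, mains) are easiest to isolate while the channel
#' covariance is still intact, and channel-wise EMD filtering would
#' distort that spatial structure. (2) Each channel is then decomposed by
#' [emd()]; IMFs whose median instantaneous frequency lies above `hiHz`
#' (residual mains, muscle) or below `loHz` (drift; the residue counts as
#' drift too) are dropped and the channel is rebuilt from the remaining
#' IMFs. Single-channel recordings skip the ICA stage with a warning.
#' Output shape and sampling rate equal the input's.
#'
#' @param rec an [EEGRecording-class].
#' @param loHz,hiHz IMF median-frequency passband (defaults 0.5 and 45 Hz,
#'   the outer rhythm band edges).
#' @param kurtosisZ,lineRatio,lineFreq artifact flagging thresholds, see
#'   [flagArtifactComponents()].
#' @param seed seed for the ICA start.
#' @return the denoised [EEGRecording-class].
#' @export
denoiseRecording <- function(rec, loHz = 0.5, hiHz = 45,
                             kurtosisZ = 2.5, lineRatio = 0.6,
                             lineFreq = 50, seed = 1L) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  data <- rec@data

  if (nrow(data) < 2) {
    warning("single-channel recording: skipping the FastICA stage")
  } else {
    ica <- fastica(data, seed = seed)
    ica <- flagArtifactComponents(ica, rec, kurtosisZ = kurtosisZ,
                                  lineRatio = lineRatio, lineFreq = lineFreq)
    data <- removeFlaggedComponents(ica)
  }

  cleaned <- t(apply(data, 1, function(x) {
    d <- emd(x)
    if (!d$nImfs) return(x - d$residue)
    keep <- vapply(d$imfs, function(imf) {
      f <- medianImfFrequency(imf, fs)
      f >= loHz && f <= hiHz
    }, TRUE)
    if (!any(keep)) return(numeric(length(x)))
    Reduce(`+`, d$imfs[keep])
  }))
  initialize(rec, data = cleaned)
}

#' Cut recordings into fixed-length labelled epochs
#'
#' Sliding windows of `round(epochS * fs)` samples with stride
#' `round(epochS * fs * (1 - overlap))`; a trailing partial window is
#' dropped. Labels and subject ids are inherited from each recording. A
#' recording shorter than one epoch contributes zero epochs, with a
#' warning.
#'
#' @param recs a list of [EEGRecording-class] objects (all with the same
#'   sampling rate and channel count), or a single recording.
#' @param epochS epoch length in seconds; `epochS * fs` must be >= 64.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return an [EpochSet-class].
#' @examples
#' p <- defaultProfiles()[[1]]
#' rec <- generateRecording(p, 12, 256, 2, seed = 1)
#' segmentEpochs(list(rec), epochS = 4)   # 3 epochs of 1024 samples
#' @export
segmentEpochs <- function(recs, epochS = 4, overlap = 0) {
  if (is(recs, "EEGRecording")) recs <- list(recs)
  stopifnot(length(recs) >= 1, all(vapply(recs, is, TRUE, "EEGRecording")))
  fs <- recs[[1]]@fs
  nCh <- nrow(recs[[1]]@data)
  len <- round(epochS * fs)
  if (len < 64) stop("epochS * fs must be >= 64 samples", call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("overlap must lie in [0, 1)", call. = FALSE)
  stride <- max(1L, round(len * (1 - overlap)))

  chunks <- list(); labels <- integer(); subjects <- character()
  for (rec in recs) {
    n <- ncol(rec@data)
    if (n < len) {
      warning(sprintf("recording %s/%d shorter than one epoch: skipped",
                      rec@subjectId, rec@conditionId))
      next
    }
    starts <- seq(1L, n - len + 1L, by = stride)
    for (s in starts) {
      chunks[[length(chunks) + 1L]] <- rec@data[, s:(s + len - 1L),
                                                drop = FALSE]
      labels <- c(labels, rec@conditionId)
      subjects <- c(subjects, rec@subjectId)
    }
  }
  epochs <- array(0, dim = c(length(chunks), nCh, len))
  for (i in seq_along(chunks)) epochs[i, , ] <- chunks[[i]]
  new("EpochSet", epochs = epochs, labels = labels,
      subjectIds = subjects, fs = fs)
}
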