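## Epoch-level feature assembly: 25 sliding-average sample entropy values
## followed by 25 windowed FBER percentages per epoch.

featureColumnNames <- function(nEntropyWindows = 25, nFberWindows = 5) {
  c(sprintf("sampen_w%02d", seq_len(nEntropyWindows)),
    as.vector(vapply(seq_len(nFberWindows),
                     function(wi) sprintf("fber_w%d_%s", wi, rhythmNames()),
                     character(5))))
}

#' Build the epoch-by-feature matrix
#'
#' For every epoch, each channel yields 25 sliding-average sample entropy
#' values ([slidingSampleEntropy()]) and 25 windowed FBER percentages
#' ([slidingFber()]); the per-channel 50-vectors are averaged across
#' channels into one row. Epochs for which any feature fails (constant
#' window, zero energy, non-finite entropy) are dropped with a warning
#' naming the reason; it is an error if every epoch is dropped.
#'
#' The matrix is returned unstandardized (FBER columns in percent,
#' entropy in nats); standardization statistics are fitted on training rows
#' only inside [trainDBN()].
#'
#' @param epochs an [EpochSet-class].
#' @param m,r sample entropy parameters.
#' @param bands rhythm band edges.
#' @param nEntropyWindows,nFberWindows feature window counts (defaults 25
#'   and 5, giving the 50-column layout).
#' @param channelMode `"average"` (default) averages feature vectors across
#'   channels; `"first"` uses channel 1 only.
#' @return a [FeatureMatrix-class].
#' @export
buildFeatureMatrix <- function(epochs, m = 2, r = 0.2,
                               bands = rhythmBands(),
                               nEntropyWindows = 25, nFberWindows = 5,
                               channelMode = c("average", "first")) {
  stopifnot(is(epochs, "EpochSet"))
  channelMode <- match.arg(channelMode)
  d <- dim(epochs@epochs)
  if (!d[1]) stop("EpochSet is empty", call. = FALSE)
  fs <- epochs@fs
  p <- nEntropyWindows + 5 * nFberWindows

  rows <- matrix(NA_real_, d[1], p)
  for (i in seq_len(d[1])) {
    chs <- if (channelMode == "first") 1L else seq_len(d[2])
    vecs <- try(vapply(chs, function(ch) {
      x <- epochs@epochs[i, ch, ]
      c(slidingSampleEntropy(x, nEntropyWindows, m, r),
        slidingFber(x, fs, bands, nFberWindows))
    }, numeric(p)), silent = TRUE)
    if (inherits(vecs, "try-error")) {
      warning(sprintf("epoch %d dropped: %s", i,
                      trimws(attr(vecs, "condition")$message)))
      next
    }
    v <- rowMeans(vecs)
    if (all(is.finite(v))) rows[i, ] <- v
    else warning(sprintf("epoch %d dropped: non-finite feature value", i))
  }

  keep <- which(stats::complete.cases(rows))
  if (!length(keep)) stop("all epochs dropped", call. = FALSE)
  new("FeatureMatrix",
      X = rows[keep, , drop = FALSE],
      y = epochs@labels[keep],
      subjectIds = epochs@subjectIds[keep],
      columnNames = featureColumnNames(nEntropyWindows, nFberWindows))
}

## z-score columns using statistics from the rows in trainIdx only.
standardizeFeatures <- function(X, trainIdx = seq_len(nrow(X))) {
  center <- colMeans(X[trainIdx, , drop = FALSE])
  scale <- apply(X[trainIdx, , drop = FALSE], 2, sd)
  scale[scale == 0] <- 1
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}
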