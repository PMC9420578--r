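## Reporting utilities: confusion matrix, per-subject accuracy, band-energy
## group comparison and transient-frequency profiles.

#' Row-normalized confusion matrix
#'
#' Counts are tallied with rows as true condition and columns as predicted,
#' then each row is divided by its total and expressed in percent, the
#' layout in which per-condition accuracy is the diagonal. An empty row
#' (condition never observed) is returned as zeros with a warning.
#'
#' @param trueLabels,predictedLabels equal-length integer vectors with
#'   values in `0 .. nClasses - 1`.
#' @param nClasses number of classes (default 5).
#' @param percent return percentages (default) or raw counts.
#' @return an `nClasses x nClasses` matrix.
#' @export
confusionMatrix <- function(trueLabels, predictedLabels, nClasses = 5,
                            percent = TRUE) {
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must have equal length", call. = FALSE)
  lab <- c(trueLabels, predictedLabels)
  if (any(lab < 0 | lab > nClasses - 1))
    stop("label out of range 0..nClasses-1", call. = FALSE)
  cm <- matrix(0, nClasses, nClasses,
               dimnames = list(true = 0:(nClasses - 1),
                               predicted = 0:(nClasses - 1)))
  for (i in seq_along(trueLabels))
    cm[trueLabels[i] + 1L, predictedLabels[i] + 1L] <-
      cm[trueLabels[i] + 1L, predictedLabels[i] + 1L] + 1
  if (!percent) return(cm)
  rs <- rowSums(cm)
  if (any(rs == 0))
    warning("empty confusion row(s): ",
            paste(which(rs == 0) - 1L, collapse = ", "))
  out <- cm
  out[rs > 0, ] <- cm[rs > 0, , drop = FALSE] / rs[rs > 0] * 100
  out
}

#' Per-subject classification accuracy
#'
#' @param trueLabels,predictedLabels,subjectIds aligned vectors, one entry
#'   per classified epoch.
#' @return list with `perSubject` (named percentages) and `summary`
#'   (named numeric: mean, min, max).
#' @export
perSubjectAccuracy <- function(trueLabels, predictedLabels, subjectIds) {
  stopifnot(length(trueLabels) == length(predictedLabels),
            length(trueLabels) == length(subjectIds))
  correct <- trueLabels == predictedLabels
  acc <- vapply(split(correct, subjectIds), function(v) mean(v) * 100, 0)
  list(perSubject = acc,
       summary = c(mean = mean(acc), min = min(acc), max = max(acc)))
}

#' Per-band group comparison of band energies
#'
#' Plain two-sample (Welch) or paired t-test per rhythm band, two-sided.
#' Inputs are per-subject band energies, e.g. column-bound [fber()] or
#' [bandEnergy()] summaries for two groups or two time points.
#'
#' @param groupA,groupB matrices `[n_subjects x n_bands]` with matching
#'   band columns (vectors are treated as one band).
#' @param paired paired test (requires equal n, matched order).
#' @param bonferroni apply Bonferroni correction across bands.
#' @return data.frame with one row per band: t statistic, p value and the
#'   two group means.
#' @examples
#' a <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("delta", "alpha")))
#' bandEnergyComparison(a, a + 5, paired = TRUE)
#' @export
bandEnergyComparison <- function(groupA, groupB, paired = FALSE,
                                 bonferroni = FALSE) {
  if (is.vector(groupA)) groupA <- matrix(groupA, ncol = 1)
  if (is.vector(groupB)) groupB <- matrix(groupB, ncol = 1)
  if (ncol(groupA) != ncol(groupB))
    stop("groups must have matching band columns", call. = FALSE)
  if (nrow(groupA) < 2 || nrow(groupB) < 2)
    stop("need n >= 2 per group", call. = FALSE)
  if (paired && nrow(groupA) != nrow(groupB))
    stop("paired comparison requires equal group sizes", call. = FALSE)
  bands <- colnames(groupA)
  if (is.null(bands)) bands <- paste0("band", seq_len(ncol(groupA)))

  rows <- lapply(seq_len(ncol(groupA)), function(j) {
    a <- groupA[, j]; b <- groupB[, j]
    if (paired && var(a - b) == 0) {
      if (all(a == b))                       # no difference anywhere: null
        return(data.frame(band = bands[j], t = 0, p = 1,
                          meanA = mean(a), meanB = mean(b)))
      stop("zero variance of paired differences for band ", bands[j],
           call. = FALSE)
    }
    if (!paired && var(a) == 0 && var(b) == 0)
      stop("zero variance in both groups for band ", bands[j], call. = FALSE)
    tt <- t.test(a, b, paired = paired, var.equal = FALSE)
    data.frame(band = bands[j], t = unname(tt$statistic),
               p = unname(tt$p.value), meanA = mean(a), meanB = mean(b))
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p <- p.adjust(out$p, "bonferroni")
  out
}

#' Transient (instantaneous) frequency profile of two conditions
#'
#' For every epoch of the two conditions, computes the amplitude-weighted
#' mean instantaneous frequency over time from the Hilbert-Huang analysis
#' (channel 1: [emd()] per epoch, [hilbertInstantaneous()] per IMF,
#' weights proportional to squared instantaneous amplitude). Returns each
#' condition's median curve over epochs and the fraction of time points at
#' which condition A's median frequency exceeds condition B's.
#'
#' @param epochs an [EpochSet-class].
#' @param conditionA,conditionB condition ids, both present in `epochs`.
#' @return list with `curveA`, `curveB` (Hz, length = epoch samples) and
#'   `dominanceFraction`.
#' @export
transientFrequencyProfile <- function(epochs, conditionA, conditionB) {
  stopifnot(is(epochs, "EpochSet"))
  fs <- epochs@fs
  curveFor <- function(cond) {
    idx <- which(epochs@labels == cond)
    if (!length(idx)) stop("condition ", cond, " not present", call. = FALSE)
    curves <- vapply(idx, function(i) {
      x <- epochs@epochs[i, 1, ]
      d <- emd(x)
      if (!d$nImfs) return(rep(0, length(x)))
      num <- numeric(length(x)); den <- numeric(length(x))
      for (imf in d$imfs) {
        h <- hilbertInstantaneous(imf, fs)
        w <- h$amplitude^2
        num <- num + w * h$frequencyHz
        den <- den + w
      }
      num / pmax(den, .Machine$double.xmin)
    }, numeric(dim(epochs@epochs)[3]))
    apply(curves, 1, median)
  }
  a <- curveFor(conditionA)
  b <- curveFor(conditionB)
  ## ties count half, so comparing a condition with itself gives 0.5
  list(curveA = a, curveB = b,
       dominanceFraction = mean(a > b) + 0.5 * mean(a == b))
}
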