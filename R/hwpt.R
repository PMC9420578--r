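## Harmonic wavelet packet transform: harmonic (Newland) wavelets are ideal
## boxcar filters in frequency, so the transform is an exact FFT-bin
## partition. This makes Parseval hold to machine precision.

#' HWPTCoefficients: harmonic wavelet packet coefficients
#'
#' Complex coefficient sequences, one per rhythm band plus a `rest` band
#' covering the remainder of `[0, fs/2]` so the bands tile the spectrum.
#' Each sequence is the inverse FFT of the signal's positive-frequency bins
#' inside the band (an analytic band signal); its squared modulus doubled
#' is the band's energy density over time.
#'
#' @slot coeffs named list of complex vectors (one per band, plus `rest`).
#' @slot fs sampling rate, Hz.
#' @slot bandEdgesHz named list of `c(low, high)` per band.
#' @slot restCorrection energy shared by the DC and Nyquist bins, which
#'   belong to `rest` and must not be double-counted.
#' @slot totalEnergy time-domain energy `sum(x^2)` of the analysed signal.
#' @export
setClass("HWPTCoefficients",
  representation(coeffs = "list", fs = "numeric", bandEdgesHz = "list",
                 restCorrection = "numeric", totalEnergy = "numeric"))

setMethod("show", "HWPTCoefficients", function(object) {
  cat(sprintf("HWPTCoefficients: %d band(s), %d samples @ %g Hz\n",
              length(object@coeffs), length(object@coeffs[[1]]), object@fs))
})

#' Harmonic wavelet packet transform
#'
#' Computes the FFT of `signal`, partitions the positive-frequency bins
#' into the rhythm bands (bin j belongs to band `[low, high)` when
#' `low <= j*fs/n < high`; everything else, including DC and Nyquist, goes
#' to the `rest` band) and inverse-transforms each partition into a complex
#' coefficient sequence. The partition is orthogonal, so summed band
#' energies equal the time-domain energy exactly.
#'
#' @param signal finite numeric vector; must be long enough to resolve the
#'   narrowest band (`length >= 2 * fs / min(bandwidth)`).
#' @param fs sampling rate, Hz.
#' @param bands rhythm band edges, see [rhythmBands()].
#' @return an [HWPTCoefficients-class].
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 4, by = 1 / 256))[-1]
#' h <- harmonicWaveletPacket(x, 256)
#' bandEnergy(h, "alpha") / sum(x^2)    # ~1: a 10 Hz tone is all alpha
#' @export
harmonicWaveletPacket <- function(signal, fs, bands = rhythmBands()) {
  stopifnotFinite(signal, "signal")
  validateBands(bands)
  if (maxBandEdge(bands) > fs / 2)
    stop("band edge above the Nyquist frequency", call. = FALSE)
  minWidth <- min(vapply(bands, function(b) b[2] - b[1], 0))
  n <- length(signal)
  if (n < 2 * fs / minWidth)
    stop(sprintf("signal too short: need >= %d samples to resolve a %g Hz band",
                 ceiling(2 * fs / minWidth), minWidth), call. = FALSE)

  X <- fft(signal)
  nyq <- floor(n / 2)                      # positive bins are j = 0 .. nyq
  j <- 0:nyq
  f <- j * fs / n
  assign <- rep("rest", length(j))
  for (b in names(bands))
    assign[f >= bands[[b]][1] & f < bands[[b]][2]] <- b
  assign[j == 0] <- "rest"                 # DC is never a rhythm
  if (n %% 2 == 0) assign[j == nyq] <- "rest"

  coeffs <- list()
  for (b in c(names(bands), "rest")) {
    Z <- complex(n)
    sel <- j[assign == b] + 1L
    Z[sel] <- X[sel]
    coeffs[[b]] <- fft(Z, inverse = TRUE) / n
  }
  corr <- Mod(X[1])^2 / n +
    if (n %% 2 == 0) Mod(X[nyq + 1L])^2 / n else 0

  edges <- c(bands, list(rest = c(NA_real_, NA_real_)))
  new("HWPTCoefficients", coeffs = coeffs, fs = fs, bandEdgesHz = edges,
      restCorrection = corr, totalEnergy = sum(signal^2))
}

#' Rhythm band energy from HWPT coefficients
#'
#' The energy of rhythm `p` is the sum over time of the squared magnitudes
#' of its wavelet coefficients (doubled, because the analytic coefficient
#' sequences carry only the positive-frequency half of a real signal's
#' spectrum). With `perSample = TRUE` the energy density over the time
#' index is returned instead of its sum.
#'
#' @param coeffs an [HWPTCoefficients-class].
#' @param p band name: one of the five rhythms or `"rest"`.
#' @param perSample return the per-time-index energy vector instead of the
#'   scalar total.
#' @return non-negative scalar (or vector when `perSample`).
#' @export
bandEnergy <- function(coeffs, p, perSample = FALSE) {
  stopifnot(is(coeffs, "HWPTCoefficients"))
  if (!p %in% names(coeffs@coeffs))
    stop("unknown rhythm: ", p, call. = FALSE)
  dens <- 2 * Mod(coeffs@coeffs[[p]])^2
  if (perSample) return(dens)
  e <- sum(dens)
  if (p == "rest") e <- e - coeffs@restCorrection   # DC/Nyquist counted once
  e
}

#' Frequency band energy ratio (FBER)
#'
#' The percentage of rhythm energy carried by each of the five bands:
#' `FBER_p = E_p / sum_p(E_p) * 100`. The five values sum to exactly 100.
#'
#' @param epoch finite numeric vector (one channel of one epoch).
#' @param fs sampling rate, Hz.
#' @param bands rhythm band edges.
#' @return named numeric(5) of percentages.
#' @export
fber <- function(epoch, fs, bands = rhythmBands()) {
  h <- harmonicWaveletPacket(epoch, fs, bands)
  e <- vapply(rhythmNames(), function(p) bandEnergy(h, p), 0)
  tot <- sum(e)
  if (tot == 0) stop("zero total energy in epoch", call. = FALSE)
  e / tot * 100
}

#' Windowed FBER profile of an epoch
#'
#' Divides the epoch into `nWindows` equal non-overlapping windows and
#' concatenates each window's five-band FBER, window-major
#' (window 1 delta..gamma, window 2 delta..gamma, ...), yielding
#' `5 * nWindows` values.
#'
#' @param epoch finite numeric vector.
#' @param fs sampling rate, Hz.
#' @param bands rhythm band edges.
#' @param nWindows number of windows (default 5, giving 25 values).
#' @return named numeric of length `5 * nWindows`.
#' @export
slidingFber <- function(epoch, fs, bands = rhythmBands(), nWindows = 5) {
  n <- length(epoch)
  len <- floor(n / nWindows)
  out <- numeric(0)
  for (wi in seq_len(nWindows)) {
    seg <- epoch[((wi - 1) * len + 1):(wi * len)]
    v <- fber(seg, fs, bands)
    names(v) <- sprintf("fber_w%d_%s", wi, rhythmNames())
    out <- c(out, v)
  }
  out
}
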