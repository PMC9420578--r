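## Empirical mode decomposition (Huang sifting, cubic-spline envelopes with
## mirror extension) and Hilbert instantaneous amplitude/frequency.

localMaxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

## Cubic-spline envelope through the extrema, with up to 3 extrema mirrored
## past each end to curb end swings.
splineEnvelope <- function(idx, val, n) {
  k <- min(3L, length(idx))
  pre  <- 2 - rev(idx[seq_len(k)])
  post <- 2 * n - rev(rev(idx)[seq_len(k)])
  xi <- c(pre, idx, post)
  yi <- c(rev(val[seq_len(k)]), val, rev(rev(val)[seq_len(k)]))
  keep <- !duplicated(xi)
  spline(xi[keep], yi[keep], xout = seq_len(n), method = "fmm")$y
}

countExtrema <- function(x) length(localMaxima(x)) + length(localMaxima(-x))

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by classic
#' sifting: at each step the mean of the cubic-spline envelopes through the
#' local maxima and minima is subtracted until the Cauchy standard-deviation
#' criterion falls below `sdStop`. Decomposition stops when the residue has
#' fewer than 3 extrema or `maxImfs` IMFs have been extracted. By
#' construction `sum(imfs) + residue` reproduces the input to machine
#' precision.
#'
#' @param signal finite numeric vector, length >= 16.
#' @param maxImfs maximum number of IMFs to extract.
#' @param sdStop sifting stop threshold on the relative change between
#'   consecutive sift iterates (classic value 0.2).
#' @return a list with `imfs` (list of numeric vectors, possibly empty),
#'   `residue` (numeric vector) and `nImfs`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 2, by = 1 / 256))
#' d <- emd(x)
#' abs(cor(d$imfs[[1]], x)) > 0.99
#' @export
emd <- function(signal, maxImfs = 10, sdStop = 0.2) {
  if (length(signal) < 16) stop("signal must have length >= 16", call. = FALSE)
  stopifnotFinite(signal, "signal")
  n <- length(signal)
  imfs <- list()
  residue <- signal

  while (length(imfs) < maxImfs && countExtrema(residue) >= 3) {
    h <- residue
    for (sift in seq_len(50)) {
      mx <- localMaxima(h); mn <- localMaxima(-h)
      if (length(mx) < 2 || length(mn) < 2) break
      upper <- splineEnvelope(mx, h[mx], n)
      lower <- splineEnvelope(mn, h[mn], n)
      m <- (upper + lower) / 2
      hNew <- h - m
      sd <- sum((h - hNew)^2) / max(sum(h^2), .Machine$double.xmin)
      h <- hNew
      if (sd < sdStop) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residue <- residue - h
  }
  list(imfs = imfs, residue = residue, nImfs = length(imfs))
}

## FFT analytic signal (positive frequencies doubled).
analyticSignal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous amplitude and frequency of one IMF
#'
#' Hilbert analysis: amplitude is the modulus of the analytic signal and
#' frequency the unwrapped-phase derivative divided by 2*pi, clipped to
#' `[0, fs/2]`.
#'
#' @param imf finite numeric vector, length >= 16.
#' @param fs sampling rate in Hz.
#' @return list with `amplitude` and `frequencyHz`, both the length of
#'   `imf`.
#' @export
hilbertInstantaneous <- function(imf, fs) {
  if (length(imf) < 16) stop("imf must have length >= 16", call. = FALSE)
  stopifnotFinite(imf, "imf")
  z <- analyticSignal(imf)
  amp <- Mod(z)
  phase <- Arg(z)
  dp <- diff(phase)
  dp <- (dp + pi) %% (2 * pi) - pi          # unwrap increments to (-pi, pi]
  freq <- c(dp, dp[length(dp)]) * fs / (2 * pi)
  freq <- pmin(pmax(freq, 0), fs / 2)
  list(amplitude = amp, frequencyHz = freq)
}

## Median instantaneous frequency of an IMF, excluding 5% edges.
medianImfFrequency <- function(imf, fs) {
  if (all(imf == 0)) return(0)
  h <- hilbertInstantaneous(imf, fs)
  n <- length(imf)
  edge <- max(1L, floor(0.05 * n))
  median(h$frequencyHz[(edge + 1L):(n - edge)])
}
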