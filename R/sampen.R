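## Sample entropy (Richman-Moorman) and its sliding-average profile.

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` is the number of template pairs of
#' length `m` within Chebyshev distance `r * sd(signal)` and `A` the same
#' count for length `m + 1`. Templates start at `i = 1 .. N - m` for both
#' lengths and self-matches are excluded. Returns `Inf` when no pair
#' matches at length `m + 1` (a perfectly unpredictable signal at this
#' tolerance).
#'
#' @param signal finite numeric vector, length >= m + 2, non-constant.
#' @param m embedding dimension (default 2).
#' @param r tolerance as a fraction of the signal's standard deviation
#'   (default 0.2).
#' @return a non-negative scalar (possibly `Inf`).
#' @examples
#' sampleEntropy(rep(c(1, 2, 3), 20))       # near 0: fully regular
#' @export
sampleEntropy <- function(signal, m = 2, r = 0.2) {
  n <- length(signal)
  if (n < m + 2) stop("signal must have length >= m + 2", call. = FALSE)
  stopifnotFinite(signal, "signal")
  s <- sd(signal)
  if (s == 0) stop("zero variance", call. = FALSE)
  tol <- r * s

  nt <- n - m                     # template count for both lengths
  ## Chebyshev distances between length-m templates, accumulated by offset
  D <- matrix(0, nt, nt)
  for (t in 0:(m - 1)) {
    seg <- signal[(1 + t):(nt + t)]
    D <- pmax(D, abs(outer(seg, seg, "-")))
  }
  B <- (sum(D <= tol) - nt) / 2   # unordered pairs, self-matches excluded
  seg <- signal[(1 + m):(nt + m)]
  D <- pmax(D, abs(outer(seg, seg, "-")))
  A <- (sum(D <= tol) - nt) / 2
  if (B == 0 || A == 0) return(Inf)
  -log(A / B)
}

#' Sliding-average sample entropy profile of an epoch
#'
#' The epoch is divided into `nWindows` windows of equal length
#' `floor(2 * N / (nWindows + 1))` sliding with 50% overlap so they span
#' the epoch. Sample entropy is computed per window and smoothed by a
#' two-window running mean (the first window passes through), giving the
#' sliding average.
#'
#' @param epoch finite numeric vector.
#' @param nWindows number of windows (default 25).
#' @param m,r sample entropy parameters, see [sampleEntropy()].
#' @return numeric of length `nWindows`.
#' @export
slidingSampleEntropy <- function(epoch, nWindows = 25, m = 2, r = 0.2) {
  n <- length(epoch)
  minLen <- nWindows * (m + 2)
  if (n < minLen)
    stop(sprintf("epoch too short: need >= %d samples for %d windows",
                 minLen, nWindows), call. = FALSE)
  len <- floor(2 * n / (nWindows + 1))
  stride <- floor(len / 2)
  raw <- vapply(seq_len(nWindows), function(wi) {
    start <- (wi - 1L) * stride + 1L
    w <- epoch[start:(start + len - 1L)]
    if (sd(w) == 0)
      stop(sprintf("zero variance in window %d", wi), call. = FALSE)
    sampleEntropy(w, m = m, r = r)
  }, 0)
  out <- raw
  if (nWindows > 1)
    out[-1] <- (raw[-1] + raw[-nWindows]) / 2
  names(out) <- sprintf("sampen_w%02d", seq_len(nWindows))
  out
}
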