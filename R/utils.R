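#' @importFrom stats rnorm runif rpois sd median cor fft t.test p.adjust
#'   quantile spline var predict complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

## Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
## state afterwards so package randomness never leaks into the session.
withLocalSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a child seed from a master seed
#'
#' All cohort- and subject-level randomness is derived from one master seed
#' through this map, so any sub-stream can be regenerated in isolation.
#' The map is affine modulo the Mersenne prime 2^31 - 1 and stays within
#' 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param index non-negative stream index.
#' @return an integer seed.
#' @export
childSeed <- function(seed, index) {
  m <- 2147483647
  s <- (as.double(seed) %% m) * 48271 + as.double(index) * 16807 + 12345
  as.integer(s %% m)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

rmsError <- function(a, b) sqrt(mean((a - b)^2))

## Excess-free sample kurtosis (normal -> 3).
kurtosisStat <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2
}

## One-sided periodogram mass of `x` inside [lo, hi) Hz (bin frequencies
## j*fs/N, j = 0 .. N-1; negative-frequency bins folded onto positives).
bandMass <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # fold to [0, fs/2]
  sum(p[f >= lo & f < hi])
}

stopifnotFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
}
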