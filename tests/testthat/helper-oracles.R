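## Independent oracles used across the suite. These deliberately do not
## share code with the package internals they check.

## O(N^2) brute-force sample entropy by direct template enumeration.
bruteSampEn <- function(x, m = 2, r = 0.2) {
  s <- sd(x)
  tol <- r * s
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= tol) B <- B + 1L
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= tol) A <- A + 1L
    }
  }
  if (A == 0L || B == 0L) return(Inf)
  -log(A / B)
}

## FFT periodogram mass of x in [lo, hi) Hz, negative frequencies folded.
oracleBandMass <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sum(p[f >= lo & f < hi])
}

## Exact log-likelihood of a small Bernoulli RBM by enumerating all
## visible and hidden states (independent of the package's own version).
oracleRBMLogLik <- function(W, bv, bh, data) {
  nv <- ncol(W); nh <- nrow(W)
  V <- as.matrix(expand.grid(rep(list(0:1), nv)))
  H <- as.matrix(expand.grid(rep(list(0:1), nh)))
  logw <- matrix(0, nrow(V), 1)
  unnorm <- vapply(seq_len(nrow(V)), function(iv) {
    v <- V[iv, ]
    sum(vapply(seq_len(nrow(H)), function(ih) {
      h <- H[ih, ]
      exp(sum(h * (W %*% v)) + sum(bv * v) + sum(bh * h))
    }, 0))
  }, 0)
  Z <- sum(unnorm)
  sum(vapply(seq_len(nrow(data)), function(i) {
    iv <- which(colSums(abs(t(V) - data[i, ])) == 0)
    log(unnorm[iv] / Z)
  }, 0))
}

## Single-band condition profile.
singleBandProfile <- function(band, regularity = 0.5, id = 0L) {
  w <- c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0)
  w[band] <- 1
  conditionProfile(id, w, regularity)
}

## Profile dominated by one band (0.6 against 0.1 each).
dominantProfile <- function(band, regularity = 0.5, id = 0L) {
  w <- c(delta = .1, theta = .1, alpha = .1, beta = .1, gamma = .1)
  w[band] <- 0.6
  conditionProfile(id, w, regularity)
}

rmsd <- function(a, b) sqrt(mean((a - b)^2))
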