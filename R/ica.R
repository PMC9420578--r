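## FastICA: symmetric fixed-point iteration with the tanh (log-cosh)
## nonlinearity after eigenvalue whitening.

#' ICADecomposition: result of FastICA on a multi-channel recording
#'
#' @slot unmixing matrix [n_components x n_channels] mapping centred
#'   channel data to sources.
#' @slot mixing matrix [n_channels x n_components]; `mixing %*% sources`
#'   reconstructs the centred data (exactly at full rank).
#' @slot sources matrix [n_components x n_samples], unit variance.
#' @slot whitening whitening matrix [n_components x n_channels].
#' @slot rowMeans channel means removed before whitening.
#' @slot componentFlags logical artifact flags, one per component.
#' @slot converged logical; FALSE if `maxIter` was reached first.
#' @export
setClass("ICADecomposition",
  representation(unmixing = "matrix", mixing = "matrix", sources = "matrix",
                 whitening = "matrix", rowMeans = "numeric",
                 componentFlags = "logical", converged = "logical"))

setMethod("show", "ICADecomposition", function(object) {
  cat(sprintf("ICADecomposition: %d component(s) from %d channel(s), %s\n",
              nrow(object@sources), nrow(object@mixing),
              if (object@converged) "converged" else "NOT converged"))
  cat(sprintf("  flagged artifact components: %s\n",
              if (any(object@componentFlags))
                paste(which(object@componentFlags), collapse = ", ")
              else "none"))
})

## Symmetric decorrelation: W <- (W W^T)^{-1/2} W.
symDecorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow = length(e$values)) %*% t(e$vectors) %*% W
}

#' FastICA blind source separation
#'
#' Centres the channel data, whitens by eigendecomposition of the channel
#' covariance (reducing to the effective rank with a warning if the
#' covariance is rank deficient), then runs the symmetric fixed-point
#' iteration with the tanh nonlinearity until the decorrelation update
#' change falls below `tol` or `maxIter` is reached. Components are ordered
#' by explained variance and signs fixed so each component's
#' largest-magnitude mixing weight is positive, removing the usual
#' sign/permutation indeterminacy.
#'
#' @param X numeric matrix [n_channels x n_samples]; needs
#'   `n_samples > 10 * n_channels`.
#' @param nComponents number of components, capped at the effective rank.
#'   The default (`NULL`) keeps the eigendirections carrying at least
#'   `varFraction` of the total variance: whitening rescales every retained
#'   direction to unit variance, so dragging near-noise directions along
#'   destabilizes the separation of the real sources.
#' @param tol convergence tolerance on the fixed-point update.
#' @param maxIter maximum fixed-point iterations.
#' @param seed integer seed for the random orthogonal start.
#' @param varFraction explained-variance cutoff used when `nComponents` is
#'   `NULL`.
#' @return an [ICADecomposition-class].
#' @export
fastica <- function(X, nComponents = NULL, tol = 1e-5, maxIter = 500,
                    seed = 1L, varFraction = 0.005) {
  X <- as.matrix(X)
  nc <- nrow(X); ns <- ncol(X)
  if (ns <= 10 * nc)
    stop("need n_samples > 10 * n_channels for a stable ICA", call. = FALSE)
  if (!is.null(nComponents) && nComponents > nc)
    stop("nComponents cannot exceed the channel count", call. = FALSE)

  mu <- rowMeans(X)
  Xc <- X - mu
  C <- Xc %*% t(Xc) / (ns - 1)
  e <- eigen(C, symmetric = TRUE)
  if (is.null(nComponents))
    nComponents <- max(1L, sum(e$values >= varFraction * sum(e$values)))
  rank <- sum(e$values > max(e$values) * 1e-10)
  if (rank < nComponents) {
    warning(sprintf(
      "rank-deficient covariance: reducing components from %d to %d",
      nComponents, rank))
    nComponents <- rank
  }
  d <- e$values[seq_len(nComponents)]
  E <- e$vectors[, seq_len(nComponents), drop = FALSE]
  K <- diag(1 / sqrt(d), nComponents) %*% t(E)       # whitening
  Xw <- K %*% Xc

  W <- withLocalSeed(seed,
    matrix(rnorm(nComponents^2), nComponents, nComponents))
  W <- symDecorrelate(W)

  converged <- FALSE
  for (it in seq_len(maxIter)) {
    U <- W %*% Xw
    G <- tanh(U)
    Wnew <- (G %*% t(Xw)) / ns - diag(rowMeans(1 - G^2), nComponents) %*% W
    Wnew <- symDecorrelate(Wnew)
    delta <- max(abs(1 - abs(rowSums(Wnew * W))))
    W <- Wnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("FastICA did not converge; returning the last iterate")

  ## order by explained variance (source rows are unit variance, so the
  ## variance a component explains is the squared norm of its mixing column)
  A <- E %*% diag(sqrt(d), nComponents) %*% t(W)     # back-projection
  ord <- order(colSums(A^2), decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  sgn <- vapply(seq_len(nComponents), function(j) {
    w <- A[, j]
    s <- sign(w[which.max(abs(w))])
    if (s == 0) 1 else s
  }, 0)
  W <- W * sgn
  A <- A %*% diag(sgn, nComponents)

  new("ICADecomposition",
      unmixing = W %*% K, mixing = A, sources = (W %*% K) %*% Xc,
      whitening = K, rowMeans = mu,
      componentFlags = rep(FALSE, nComponents),
      converged = converged)
}

#' Flag artifact independent components
#'
#' Statistical artifact identification: a component is flagged when its
#' kurtosis z-score across components exceeds `kurtosisZ` (blink-like
#' transients are strongly leptokurtic) or when the fraction of its
#' periodogram mass within +-1 Hz of `lineFreq` exceeds `lineRatio` (mains
#' interference). The z-score is robust (median and MAD across components,
#' with the MAD floored at 0.5 kurtosis units): decompositions have few
#' components, and one extreme artifact component would otherwise inflate
#' a mean/sd z-score's denominator and mask itself.
#'
#' @param ica an [ICADecomposition-class] from the same recording.
#' @param rec the [EEGRecording-class] the decomposition came from (carries
#'   the sampling rate).
#' @param kurtosisZ kurtosis z-score threshold (default 2.5).
#' @param lineRatio line-band mass fraction threshold (default 0.6).
#' @param lineFreq mains frequency in Hz (default 50).
#' @return the decomposition with `componentFlags` filled in.
#' @export
flagArtifactComponents <- function(ica, rec, kurtosisZ = 2.5,
                                   lineRatio = 0.6, lineFreq = 50) {
  stopifnot(is(ica, "ICADecomposition"), is(rec, "EEGRecording"))
  fs <- rec@fs
  S <- ica@sources
  kurt <- apply(S, 1, kurtosisStat)
  z <- if (length(kurt) > 1) {
    (kurt - median(kurt)) / max(stats::mad(kurt), 0.5)
  } else rep(0, length(kurt))
  lineFrac <- apply(S, 1, function(s) {
    tot <- bandMass(s, fs, 0, fs / 2)
    if (tot == 0) 0 else
      bandMass(s, fs, max(lineFreq - 1, 0), min(lineFreq + 1, fs / 2)) / tot
  })
  ica@componentFlags <- (z > kurtosisZ) | (lineFrac > lineRatio)
  ica
}

## Zero the flagged components and back-project to channel space.
removeFlaggedComponents <- function(ica) {
  S <- ica@sources
  S[ica@componentFlags, ] <- 0
  ica@mixing %*% S + ica@rowMeans
}
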