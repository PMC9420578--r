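## Restricted Boltzmann machines: initialization, conditionals and
## contrastive-divergence (CD-k) updates.

#' Initialize an RBM
#'
#' Weights are drawn from a seeded Gaussian with standard deviation 0.01;
#' biases start at exactly zero.
#'
#' @param nVisible,nHidden layer sizes (>= 1).
#' @param unitType visible unit type, `"gaussian"` (real-valued inputs,
#'   unit variance assumed) or `"bernoulli"`.
#' @param seed integer seed.
#' @return an [RBMParams-class].
#' @export
rbmInit <- function(nVisible, nHidden, unitType = c("gaussian", "bernoulli"),
                    seed = 1L) {
  unitType <- match.arg(unitType)
  if (nVisible < 1 || nHidden < 1) stop("layer sizes must be >= 1",
                                        call. = FALSE)
  W <- withLocalSeed(seed,
    matrix(rnorm(nHidden * nVisible, sd = 0.01), nHidden, nVisible))
  new("RBMParams", W = W, bVisible = numeric(nVisible),
      bHidden = numeric(nHidden), unitType = unitType)
}

#' Hidden activation probabilities of an RBM
#'
#' `sigmoid(W v + b_hidden)`, row-wise over a batch.
#'
#' @param rbm an [RBMParams-class].
#' @param v a visible vector, or a batch matrix `[n_samples x n_visible]`.
#' @return probabilities in (0, 1), same row layout as `v`.
#' @export
rbmHiddenProbs <- function(rbm, v) {
  if (is.vector(v)) v <- matrix(v, nrow = 1)
  if (ncol(v) != ncol(rbm@W))
    stop("v does not match n_visible", call. = FALSE)
  p <- sigmoid(v %*% t(rbm@W) + rep(rbm@bHidden, each = nrow(v)))
  if (nrow(p) == 1) drop(p) else p
}

## Visible reconstruction given hidden states: sigmoid mean for Bernoulli
## units, linear mean for Gaussian units.
rbmVisibleMean <- function(rbm, h) {
  act <- h %*% rbm@W + rep(rbm@bVisible, each = nrow(h))
  if (rbm@unitType == "bernoulli") sigmoid(act) else act
}

#' One contrastive-divergence parameter update
#'
#' Positive phase statistics come from the data batch; the negative phase
#' runs `k` seeded Gibbs steps (hidden states sampled, visible units
#' reconstructed by their conditional means). The update is
#' `dW = lr * (<v h>_data - <v h>_model) / batch_size`, with the analogous
#' bias updates.
#'
#' @param rbm an [RBMParams-class].
#' @param batch matrix `[n_samples x n_visible]`.
#' @param k number of Gibbs steps (>= 1).
#' @param lr learning rate; `lr = 0` returns `rbm` unchanged bit-exactly.
#' @param seed integer seed for the Gibbs sampling.
#' @return the updated [RBMParams-class].
#' @export
cdkUpdate <- function(rbm, batch, k = 1, lr = 0.1, seed = 1L) {
  if (is.vector(batch)) batch <- matrix(batch, nrow = 1)
  if (ncol(batch) != ncol(rbm@W))
    stop("batch does not match n_visible", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (lr == 0) return(rbm)
  n <- nrow(batch)

  withLocalSeed(seed, {
    hp0 <- sigmoid(batch %*% t(rbm@W) + rep(rbm@bHidden, each = n))
    h <- matrix(as.numeric(runif(length(hp0)) < hp0), n)
    v <- batch
    for (step in seq_len(k)) {
      v <- rbmVisibleMean(rbm, h)
      hp <- sigmoid(v %*% t(rbm@W) + rep(rbm@bHidden, each = n))
      if (step < k)
        h <- matrix(as.numeric(runif(length(hp)) < hp), n)
    }
    dW <- (t(hp0) %*% batch - t(hp) %*% v) / n
    initialize(rbm,
      W = rbm@W + lr * dW,
      bVisible = rbm@bVisible + lr * colMeans(batch - v),
      bHidden = rbm@bHidden + lr * colMeans(hp0 - hp))
  })
}

## Train one RBM for `epochs` passes over shuffled minibatches.
trainRBM <- function(rbm, X, epochs, k, lr, batchSize, seed) {
  n <- nrow(X)
  ctr <- 0L
  for (ep in seq_len(epochs)) {
    ord <- withLocalSeed(childSeed(seed, ep), sample.int(n))
    starts <- seq(1L, n, by = batchSize)
    for (s in starts) {
      idx <- ord[s:min(s + batchSize - 1L, n)]
      ctr <- ctr + 1L
      rbm <- cdkUpdate(rbm, X[idx, , drop = FALSE], k = k, lr = lr,
                       seed = childSeed(seed, 100000L + ctr))
    }
  }
  rbm
}

## Exact log-likelihood of a small Bernoulli RBM by enumerating all hidden
## and visible states. Only feasible for a handful of units; used by tests
## and sanity checks, never by training.
rbmExactLogLik <- function(rbm, data) {
  nv <- ncol(rbm@W); nh <- nrow(rbm@W)
  stopifnot(rbm@unitType == "bernoulli", nv + nh <= 20)
  states <- function(m)
    as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  V <- states(nv); H <- states(nh)
  ## energy E(v,h) = -h' W v - b' v - c' h
  M <- exp(H %*% rbm@W %*% t(V) +
             matrix(V %*% rbm@bVisible, nrow(H), nrow(V), byrow = TRUE) +
             matrix(H %*% rbm@bHidden, nrow(H), nrow(V)))
  Z <- sum(M)
  pV <- colSums(M) / Z
  idx <- apply(data, 1, function(v)
    which(colSums(abs(t(V) - v)) == 0))
  sum(log(pV[idx]))
}
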