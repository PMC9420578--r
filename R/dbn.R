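## Deep belief network: greedy layer-wise CD pretraining, softmax head,
## gradient-descent fine-tuning with full backpropagation.

#' Training configuration for the DBN
#'
#' @param layerSizes visible-to-deepest layer widths; the first entry must
#'   equal the feature dimension (50 for the standard feature layout).
#' @param cdK Gibbs steps per contrastive-divergence update.
#' @param lrPretrain pretraining learning rate (kept small because the
#'   first RBM has Gaussian visible units).
#' @param epochsPretrain CD epochs per RBM; 0 leaves the stack at its
#'   random initialization.
#' @param lrFinetune fine-tuning learning rate.
#' @param iterationsFinetune number of fine-tune iterations (full passes
#'   over the training rows).
#' @param batchSize minibatch size for both phases.
#' @param seed mandatory integer seed; the whole run is reproducible from
#'   it.
#' @param shuffleEachIteration reshuffle the training rows every
#'   fine-tune iteration.
#' @return a named list, validated.
#' @export
trainConfig <- function(layerSizes = c(50, 40, 30), cdK = 1,
                        lrPretrain = 0.01, epochsPretrain = 30,
                        lrFinetune = 0.1, iterationsFinetune = 500,
                        batchSize = 64, seed, shuffleEachIteration = TRUE) {
  if (missing(seed)) stop("seed is mandatory in trainConfig()", call. = FALSE)
  cfg <- list(layerSizes = as.integer(layerSizes), cdK = as.integer(cdK),
              lrPretrain = lrPretrain, epochsPretrain = as.integer(epochsPretrain),
              lrFinetune = lrFinetune,
              iterationsFinetune = as.integer(iterationsFinetune),
              batchSize = as.integer(batchSize), seed = as.integer(seed),
              shuffleEachIteration = isTRUE(shuffleEachIteration))
  if (length(cfg$layerSizes) < 2) stop("need at least one hidden layer",
                                       call. = FALSE)
  if (any(unlist(cfg[c("layerSizes", "cdK", "batchSize")]) < 1) ||
      cfg$lrPretrain < 0 || cfg$lrFinetune < 0 ||
      cfg$epochsPretrain < 0 || cfg$iterationsFinetune < 0)
    stop("config values must be positive", call. = FALSE)
  cfg
}

featureMatrixOf <- function(features) {
  if (is(features, "FeatureMatrix")) features@X else as.matrix(features)
}

#' Greedy layer-wise RBM pretraining
#'
#' Trains the first RBM (Gaussian visible units) on the standardized
#' feature rows, then propagates hidden probabilities upward as the data
#' for the next (Bernoulli) RBM, and so on through `layerSizes`.
#'
#' @param features a [FeatureMatrix-class] or a numeric matrix of already
#'   standardized rows.
#' @param config a [trainConfig()] list.
#' @param trainIdx rows to train on (and, for a `FeatureMatrix`, the rows
#'   whose statistics standardize the columns); default all rows.
#' @return list of [RBMParams-class], input layer first.
#' @export
pretrainDBN <- function(features, config, trainIdx = NULL) {
  X <- featureMatrixOf(features)
  if (is.null(trainIdx)) trainIdx <- seq_len(nrow(X))
  if (!length(trainIdx)) stop("empty training set", call. = FALSE)
  if (is(features, "FeatureMatrix"))
    X <- standardizeFeatures(X, trainIdx)$X
  X <- X[trainIdx, , drop = FALSE]
  sizes <- config$layerSizes
  if (sizes[1] != ncol(X))
    stop(sprintf("layerSizes[1] = %d must equal the feature dimension %d",
                 sizes[1], ncol(X)), call. = FALSE)

  rbms <- vector("list", length(sizes) - 1L)
  input <- X
  for (l in seq_along(rbms)) {
    unit <- if (l == 1L) "gaussian" else "bernoulli"
    rbm <- rbmInit(sizes[l], sizes[l + 1L], unit,
                   seed = childSeed(config$seed, 7000L + l))
    if (config$epochsPretrain > 0)
      rbm <- trainRBM(rbm, input, config$epochsPretrain, config$cdK,
                      config$lrPretrain, config$batchSize,
                      seed = childSeed(config$seed, 8000L + l))
    rbms[[l]] <- rbm
    input <- rbmHiddenProbs(rbm, input)
    if (is.vector(input)) input <- matrix(input, nrow = 1)
  }
  rbms
}

#' Softmax class probabilities
#'
#' `p(y = j | x) = exp(theta_j' x) / sum_i exp(theta_i' x)`, computed with
#' max-subtraction so large activations cannot overflow. Adding the same
#' vector to every `theta_j` leaves the output unchanged.
#'
#' @param theta parameter matrix `[k_classes x (d + 1)]`, bias in the last
#'   column.
#' @param x a feature vector of length `d`, or a matrix `[n x d]`.
#' @return a probability vector of length `k` (or an `[n x k]` matrix),
#'   rows summing to 1.
#' @export
softmaxProbabilities <- function(theta, x) {
  if (!all(is.finite(theta))) stop("non-finite theta", call. = FALSE)
  vec <- is.vector(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop("non-finite x", call. = FALSE)
  if (ncol(x) != ncol(theta) - 1L)
    stop("x dimension must match theta columns minus the bias", call. = FALSE)
  act <- cbind(x, 1) %*% t(theta)
  act <- act - apply(act, 1, max)
  p <- exp(act)
  p <- p / rowSums(p)
  if (vec) drop(p) else p
}

## Forward pass: returns hidden activations per layer and class
## probabilities.
dbnForward <- function(rbms, theta, X) {
  acts <- vector("list", length(rbms) + 1L)
  acts[[1]] <- X
  for (l in seq_along(rbms)) {
    a <- rbmHiddenProbs(rbms[[l]], acts[[l]])
    if (is.vector(a)) a <- matrix(a, nrow = 1)
    acts[[l + 1L]] <- a
  }
  list(acts = acts, probs = softmaxProbabilities(theta, acts[[length(acts)]]))
}

## Cross-entropy loss and analytic gradients for every parameter of the
## stack (weights, hidden biases, theta). Y is a one-hot matrix.
dbnLossGrad <- function(rbms, theta, X, Y) {
  fw <- dbnForward(rbms, theta, X)
  P <- fw$probs
  if (is.vector(P)) P <- matrix(P, nrow = 1)
  n <- nrow(X)
  loss <- -mean(rowSums(Y * log(pmax(P, 1e-300))))

  top <- fw$acts[[length(fw$acts)]]
  delta <- (P - Y) / n                                 # d loss / d act_out
  gTheta <- t(delta) %*% cbind(top, 1)
  dA <- delta %*% theta[, -ncol(theta), drop = FALSE]

  gW <- vector("list", length(rbms))
  gB <- vector("list", length(rbms))
  for (l in rev(seq_along(rbms))) {
    a <- fw$acts[[l + 1L]]
    dZ <- dA * a * (1 - a)
    gW[[l]] <- t(dZ) %*% fw$acts[[l]]
    gB[[l]] <- colSums(dZ)
    dA <- dZ %*% rbms[[l]]@W
  }
  list(loss = loss, gTheta = gTheta, gW = gW, gB = gB, probs = P)
}

oneHot <- function(y, classLabels) {
  Y <- matrix(0, length(y), length(classLabels))
  Y[cbind(seq_along(y), match(y, classLabels))] <- 1
  Y
}

#' Fine-tune a DBN with its softmax head
#'
#' Supervised gradient descent: forward pass through the sigmoid layers to
#' the softmax, cross-entropy loss, full backpropagation through every
#' layer at `lrFinetune`, in seeded minibatches reshuffled each iteration
#' when `shuffleEachIteration` is set. After each iteration the training
#' mean squared error (Brier score against one-hot labels,
#' `mean over rows of sum_j (p_j - 1{y=j})^2`) and training accuracy are
#' recorded. If the loss turns non-finite the run aborts, returning the
#' state at the last finite iteration with a warning.
#'
#' @param dbn a [DBNModel-class] (e.g. from [pretrainDBN()] stacked by
#'   [trainDBN()], or assembled manually).
#' @param features a [FeatureMatrix-class] or an already standardized
#'   matrix; rows outside `trainIdx` are ignored.
#' @param config a [trainConfig()] list.
#' @param trainIdx rows to train on; default all.
#' @return list with `model` (updated [DBNModel-class]) and `trace`
#'   (list with `msePerIteration` and `trainAccuracyPerIteration`).
#' @export
finetuneDBN <- function(dbn, features, config, trainIdx = NULL) {
  X <- featureMatrixOf(features)
  y <- if (is(features, "FeatureMatrix")) features@y
       else stop("finetuneDBN needs labels: pass a FeatureMatrix or use trainDBN")
  if (is.null(trainIdx)) trainIdx <- seq_len(nrow(X))
  if (!is.null(dbn@center))
    X <- sweep(sweep(X, 2, dbn@center), 2, dbn@scale, "/")
  else if (is(features, "FeatureMatrix"))
    X <- standardizeFeatures(X, trainIdx)$X
  finetuneCore(dbn, X[trainIdx, , drop = FALSE], y[trainIdx], config)
}

finetuneCore <- function(dbn, X, y, config) {
  rbms <- dbn@rbms
  theta <- dbn@theta
  labels <- dbn@classLabels
  Y <- oneHot(y, labels)
  n <- nrow(X)
  iters <- config$iterationsFinetune
  mse <- numeric(iters)
  acc <- numeric(iters)
  lr <- config$lrFinetune

  for (it in seq_len(iters)) {
    ord <- if (config$shuffleEachIteration)
      withLocalSeed(childSeed(config$seed, 20000L + it), sample.int(n))
    else seq_len(n)
    for (s in seq(1L, n, by = config$batchSize)) {
      idx <- ord[s:min(s + config$batchSize - 1L, n)]
      g <- dbnLossGrad(rbms, theta, X[idx, , drop = FALSE],
                       Y[idx, , drop = FALSE])
      if (!is.finite(g$loss)) {
        warning(sprintf("non-finite loss at iteration %d: aborting", it))
        trace <- list(msePerIteration = mse[seq_len(it - 1L)],
                      trainAccuracyPerIteration = acc[seq_len(it - 1L)])
        dbn@rbms <- rbms; dbn@theta <- theta
        return(list(model = dbn, trace = trace))
      }
      theta <- theta - lr * g$gTheta
      for (l in seq_along(rbms)) {
        rbms[[l]]@W <- rbms[[l]]@W - lr * g$gW[[l]]
        rbms[[l]]@bHidden <- rbms[[l]]@bHidden - lr * g$gB[[l]]
      }
    }
    fw <- dbnForward(rbms, theta, X)
    P <- fw$probs
    mse[it] <- mean(rowSums((P - Y)^2))
    acc[it] <- mean(labels[max.col(P, ties.method = "first")] == y)
  }
  dbn@rbms <- rbms; dbn@theta <- theta
  list(model = dbn,
       trace = list(msePerIteration = mse, trainAccuracyPerIteration = acc))
}

#' Train a DBN end to end on a feature matrix
#'
#' Standardizes the columns using the training rows only, pretrains the
#' RBM stack ([pretrainDBN()]), attaches a zero-initialized softmax head
#' and fine-tunes the whole network ([finetuneDBN()]). The fitted
#' standardization is stored on the model, so [predictDBN()] can be
#' applied directly to raw feature rows.
#'
#' @param features a [FeatureMatrix-class].
#' @param config a [trainConfig()] list.
#' @param trainIdx training row indices (default all rows).
#' @return list with `model` ([DBNModel-class]) and `trace`.
#' @export
trainDBN <- function(features, config, trainIdx = NULL) {
  stopifnot(is(features, "FeatureMatrix"))
  if (is.null(trainIdx)) trainIdx <- seq_len(nrow(features@X))
  std <- standardizeFeatures(features@X, trainIdx)
  labels <- sort(unique(features@y))
  rbms <- pretrainDBN(std$X[trainIdx, , drop = FALSE], config)
  top <- config$layerSizes[length(config$layerSizes)]
  model <- new("DBNModel", rbms = rbms,
               theta = matrix(0, length(labels), top + 1L),
               classLabels = labels, center = std$center, scale = std$scale)
  fit <- finetuneCore(model, std$X[trainIdx, , drop = FALSE],
                      features@y[trainIdx], config)
  fit
}

#' Predict condition labels with a trained DBN
#'
#' Applies the model's stored standardization (if fitted), runs the
#' forward pass and takes the argmax class per row, breaking ties toward
#' the lowest class index.
#'
#' @param model a [DBNModel-class].
#' @param X a [FeatureMatrix-class] or numeric matrix with one row per
#'   epoch (raw, unstandardized features when the model carries
#'   standardization statistics).
#' @return list with `labels` (integer vector) and `probabilities`
#'   (`[n x k]`, rows summing to 1).
#' @export
predictDBN <- function(model, X) {
  stopifnot(is(model, "DBNModel"))
  X <- featureMatrixOf(X)
  if (length(model@rbms) && ncol(X) != ncol(model@rbms[[1]]@W))
    stop(sprintf("X has %d columns but the model expects %d",
                 ncol(X), ncol(model@rbms[[1]]@W)), call. = FALSE)
  if (!is.null(model@center))
    X <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  P <- dbnForward(model@rbms, model@theta, X)$probs
  if (is.vector(P)) P <- matrix(P, nrow = 1)
  list(labels = model@classLabels[max.col(P, ties.method = "first")],
       probabilities = P)
}

#' @describeIn predictDBN method for the generic `predict`.
#' @param object a [DBNModel-class].
#' @param newdata features to classify.
#' @param ... ignored.
#' @export
setMethod("predict", "DBNModel", function(object, newdata, ...)
  predictDBN(object, newdata))
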