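test_that("RBM initialization is seeded with zero biases", {
  r1 <- rbmInit(6, 4, "gaussian", seed = 3)
  r2 <- rbmInit(6, 4, "gaussian", seed = 3)
  expect_identical(r1@W, r2@W)
  expect_identical(dim(r1@W), c(4L, 6L))
  expect_identical(r1@bVisible, numeric(6))
  expect_identical(r1@bHidden, numeric(4))
})

test_that("hidden conditionals follow the sigmoid of the linear activation", {
  r <- rbmInit(2, 2, "bernoulli", seed = 1)
  r@W <- matrix(c(1, 0, -1, 2), 2, 2)       # rows = hidden units
  expect_equal(rbmHiddenProbs(r, c(1, 1)),
               c(1 / (1 + exp(0)), 1 / (1 + exp(-2))))
  z <- rbmInit(3, 2, "bernoulli", seed = 1)
  z@W <- matrix(0, 2, 3)
  expect_equal(rbmHiddenProbs(z, c(4, -1, 2)), c(0.5, 0.5))
  ## monotone in any visible unit with a positive weight
  r2 <- rbmInit(2, 1, "bernoulli", seed = 2)
  r2@W <- matrix(c(0.7, -0.2), 1, 2)
  p1 <- rbmHiddenProbs(r2, c(0, 1))
  p2 <- rbmHiddenProbs(r2, c(1, 1))
  expect_gt(p2, p1)
})

test_that("a zero learning rate leaves CD updates bit-exact", {
  r <- rbmInit(4, 3, "bernoulli", seed = 7)
  batch <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 2, 4, byrow = TRUE)
  expect_identical(cdkUpdate(r, batch, k = 1, lr = 0, seed = 1), r)
})

test_that("CD-1 training increases the exact log-likelihood of a tiny RBM", {
  data <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 2, 4, byrow = TRUE)
  rbm <- rbmInit(4, 3, "bernoulli", seed = 42)
  ll0 <- oracleRBMLogLik(rbm@W, rbm@bVisible, rbm@bHidden, data)
  r <- rbm
  for (ep in 1:500)
    r <- cdkUpdate(r, data, k = 1, lr = 0.1, seed = childSeed(9, ep))
  ll1 <- oracleRBMLogLik(r@W, r@bVisible, r@bHidden, data)
  expect_gt(ll1, ll0)
})

test_that("the CD-1 weight step points uphill in exact likelihood on average", {
  data <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 2, 4, byrow = TRUE)
  eps <- 1e-5
  coss <- vapply(1:10, function(s) {
    rbm <- rbmInit(4, 3, "bernoulli", seed = s)
    G <- rbm@W * 0
    for (i in 1:3) for (j in 1:4) {
      Wp <- rbm@W; Wp[i, j] <- Wp[i, j] + eps
      Wm <- rbm@W; Wm[i, j] <- Wm[i, j] - eps
      G[i, j] <- (oracleRBMLogLik(Wp, rbm@bVisible, rbm@bHidden, data) -
                    oracleRBMLogLik(Wm, rbm@bVisible, rbm@bHidden, data)) /
        (2 * eps)
    }
    up <- cdkUpdate(rbm, data, 1, 0.1, seed = s + 100)
    d <- up@W - rbm@W
    sum(d * G) / sqrt(sum(d^2) * sum(G^2))
  }, 0)
  expect_gt(mean(coss), 0)
})

test_that("greedy pretraining chains layer shapes and reduces reconstruction error", {
  X <- withr::with_seed(10, matrix(rnorm(60 * 50), 60))
  fm <- new("FeatureMatrix", X = X, y = rep(0:1, 30),
            subjectIds = rep("s", 60), columnNames = sprintf("c%d", 1:50))
  cfg0 <- trainConfig(layerSizes = c(50, 30, 20), epochsPretrain = 0, seed = 2)
  rbms0 <- pretrainDBN(fm, cfg0)
  expect_identical(dim(rbms0[[1]]@W), c(30L, 50L))
  expect_identical(dim(rbms0[[2]]@W), c(20L, 30L))
  expect_identical(rbms0[[1]]@W, rbmInit(50, 30, "gaussian",
                                         seed = childSeed(2, 7001L))@W)

  recon <- function(rbm, Z) {
    H <- rbmHiddenProbs(rbm, Z)
    H %*% rbm@W + rep(rbm@bVisible, each = nrow(Z))
  }
  wins <- vapply(1:10, function(s) {
    Xs <- withr::with_seed(s, matrix(rnorm(60 * 20), 60))
    Zs <- scale(Xs)
    c0 <- trainConfig(layerSizes = c(20, 10), epochsPretrain = 0, seed = s)
    c1 <- trainConfig(layerSizes = c(20, 10), epochsPretrain = 50,
                      lrPretrain = 0.01, batchSize = 15, seed = s)
    e0 <- sqrt(mean((recon(pretrainDBN(Zs, c0)[[1]], Zs) - Zs)^2))
    e1 <- sqrt(mean((recon(pretrainDBN(Zs, c1)[[1]], Zs) - Zs)^2))
    e1 < e0
  }, TRUE)
  expect_true(all(wins))
})

test_that("softmax probabilities are normalized, shift-invariant and logistic at k=2", {
  expect_equal(softmaxProbabilities(matrix(0, 5, 4), c(1, 2, 3)),
               rep(0.2, 5))
  theta <- withr::with_seed(1, matrix(rnorm(10), 2, 5))
  x <- c(0.3, -1, 2, 0.5)
  p <- softmaxProbabilities(theta, x)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p[1],
               1 / (1 + exp(-sum((theta[1, ] - theta[2, ]) * c(x, 1)))),
               tolerance = 1e-12)
  shifted <- theta + matrix(rep(c(3, -2, 1, 0, 5), each = 2), 2, 5)
  expect_equal(softmaxProbabilities(shifted, x), p, tolerance = 1e-12)
  ## overflow safety
  expect_equal(sum(softmaxProbabilities(theta * 500, x)), 1)
  expect_error(softmaxProbabilities(theta, c(1, NA, 0, 2)), "non-finite")
})

test_that("analytic gradients match central finite differences", {
  X <- withr::with_seed(3, matrix(rnorm(10 * 6), 10))
  y <- withr::with_seed(4, sample(0:2, 10, TRUE))
  rbms <- list(rbmInit(6, 5, "gaussian", seed = 1),
               rbmInit(5, 4, "bernoulli", seed = 2))
  theta <- withr::with_seed(5, matrix(rnorm(15, sd = 0.1), 3, 5))
  Y <- museeg:::oneHot(y, 0:2)
  g <- museeg:::dbnLossGrad(rbms, theta, X, Y)
  eps <- 1e-5

  numTheta <- theta * 0
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    numTheta[i] <- (museeg:::dbnLossGrad(rbms, tp, X, Y)$loss -
                      museeg:::dbnLossGrad(rbms, tm, X, Y)$loss) / (2 * eps)
  }
  expect_lt(max(abs(numTheta - g$gTheta)) / max(abs(g$gTheta)), 1e-6)

  for (l in 1:2) {
    numW <- rbms[[l]]@W * 0
    for (i in seq_along(numW)) {
      rp <- rbms; rp[[l]]@W[i] <- rp[[l]]@W[i] + eps
      rm <- rbms; rm[[l]]@W[i] <- rm[[l]]@W[i] - eps
      numW[i] <- (museeg:::dbnLossGrad(rp, theta, X, Y)$loss -
                    museeg:::dbnLossGrad(rm, theta, X, Y)$loss) / (2 * eps)
    }
    expect_lt(max(abs(numW - g$gW[[l]])) / max(abs(g$gW[[l]])), 1e-6)

    numB <- rbms[[l]]@bHidden * 0
    for (i in seq_along(numB)) {
      rp <- rbms; rp[[l]]@bHidden[i] <- rp[[l]]@bHidden[i] + eps
      rm <- rbms; rm[[l]]@bHidden[i] <- rm[[l]]@bHidden[i] - eps
      numB[i] <- (museeg:::dbnLossGrad(rp, theta, X, Y)$loss -
                    museeg:::dbnLossGrad(rm, theta, X, Y)$loss) / (2 * eps)
    }
    expect_lt(max(abs(numB - g$gB[[l]])) / max(abs(g$gB[[l]])), 1e-6)
  }
})

test_that("a zero fine-tune learning rate freezes the MSE trace", {
  X <- withr::with_seed(6, matrix(rnorm(40 * 50), 40))
  fm <- new("FeatureMatrix", X = X, y = rep(0:1, 20),
            subjectIds = rep("s", 40), columnNames = sprintf("c%d", 1:50))
  cfg <- trainConfig(epochsPretrain = 0, lrFinetune = 0,
                     iterationsFinetune = 5, seed = 3)
  fit <- trainDBN(fm, cfg)
  expect_equal(length(unique(fit$trace$msePerIteration)), 1L)
})

test_that("linearly separable classes are learned to perfection", {
  for (s in 1:10) {
    X <- withr::with_seed(s, rbind(matrix(rnorm(60 * 50, 1), 60),
                                   matrix(rnorm(60 * 50, -1), 60)))
    fm <- new("FeatureMatrix", X = X, y = rep(0:1, each = 60),
              subjectIds = rep("s", 120), columnNames = sprintf("c%d", 1:50))
    cfg <- trainConfig(layerSizes = c(50, 40, 30), epochsPretrain = 30,
                       iterationsFinetune = 500, seed = s)
    fit <- trainDBN(fm, cfg)
    expect_equal(tail(fit$trace$trainAccuracyPerIteration, 1), 1)
    pr <- predictDBN(fit$model, fm)
    expect_identical(pr$labels, fm@y)
  }
})

test_that("prediction is a normalized, deterministic argmax", {
  X <- withr::with_seed(8, matrix(rnorm(30 * 50), 30))
  fm <- new("FeatureMatrix", X = X, y = rep(0:2, 10),
            subjectIds = rep("s", 30), columnNames = sprintf("c%d", 1:50))
  cfg <- trainConfig(epochsPretrain = 2, iterationsFinetune = 10, seed = 5)
  fit <- trainDBN(fm, cfg)
  pr <- predictDBN(fit$model, X)
  expect_equal(rowSums(pr$probabilities), rep(1, 30), tolerance = 1e-12)
  pr2 <- predictDBN(fit$model, X)
  expect_identical(pr$labels, pr2$labels)
  expect_identical(pr$probabilities, pr2$probabilities)
  expect_error(predictDBN(fit$model, X[, 1:20]), "expects")
})

test_that("the full train-and-predict run is reproducible from the seed", {
  X <- withr::with_seed(9, matrix(rnorm(50 * 50), 50))
  fm <- new("FeatureMatrix", X = X, y = rep(0:4, 10),
            subjectIds = rep(c("a", "b"), 25), columnNames = sprintf("c%d", 1:50))
  cfg <- trainConfig(epochsPretrain = 3, iterationsFinetune = 20, seed = 11)
  f1 <- trainDBN(fm, cfg)
  f2 <- trainDBN(fm, cfg)
  expect_identical(f1$model@theta, f2$model@theta)
  expect_identical(f1$model@rbms[[1]]@W, f2$model@rbms[[1]]@W)
  expect_identical(f1$trace$msePerIteration, f2$trace$msePerIteration)
})
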