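test_that("a pure tone is its own intrinsic mode function", {
  x <- sin(2 * pi * 10 * seq(0, 2, by = 1 / 256))[-1]
  d <- emd(x)
  expect_gte(abs(cor(d$imfs[[1]], x)), 0.99)
})

test_that("constant signals decompose to an empty IMF list", {
  d <- emd(rep(5, 64))
  expect_identical(d$nImfs, 0L)
  expect_equal(d$residue, rep(5, 64))
})

test_that("EMD reconstruction is complete on random signals", {
  for (s in 1:30) {
    x <- withr::with_seed(s, rnorm(512))
    d <- emd(x)
    back <- Reduce(`+`, c(d$imfs, list(d$residue)))
    expect_lte(max(abs(back - x)), 1e-8 * (max(x) - min(x)))
  }
})

test_that("Hilbert analysis recovers the frequency and amplitude of a tone", {
  t_ <- seq(0, 2, by = 1 / 256)[-1]
  h <- hilbertInstantaneous(sin(2 * pi * 8 * t_), 256)
  n <- length(t_)
  edge <- floor(0.05 * n)
  core <- (edge + 1):(n - edge)
  expect_gte(median(h$frequencyHz[core]), 7.8)
  expect_lte(median(h$frequencyHz[core]), 8.2)
  expect_gte(median(h$amplitude[core]), 0.98)
  expect_lte(median(h$amplitude[core]), 1.02)

  hz <- hilbertInstantaneous(rep(0, 64), 256)
  expect_equal(hz$amplitude, rep(0, 64))
})

test_that("FastICA recovers known sources from a fixed mixing", {
  n <- 5000
  t_ <- seq_len(n) / 1000
  S <- rbind(sin(2 * pi * 5 * t_),
             2 * ((t_ * 3) %% 1) - 1,
             withr::with_seed(5, runif(n, -1, 1)))
  A <- matrix(c(1, .5, .2, .1, .3, 1, .4, .2, .2, .3, 1, .6), 4, 3)
  X <- A %*% S
  ica <- fastica(X, nComponents = 3, seed = 1)
  cors <- abs(cor(t(ica@sources), t(S)))
  expect_true(all(apply(cors, 2, max) >= 0.95))
  ## reconstruction identity at full retained rank
  Xc <- X - rowMeans(X)
  expect_lt(norm(ica@mixing %*% ica@sources - Xc, "F") / norm(Xc, "F"), 1e-6)
  ## unmixing rows are unit-norm in whitened space: sources have unit sd
  expect_equal(apply(ica@sources, 1, sd), rep(1, 3), tolerance = 1e-2)

  ica2 <- fastica(X, nComponents = 3, seed = 1)
  expect_identical(ica@unmixing, ica2@unmixing)
})

test_that("already-independent non-Gaussian rows pass through FastICA unchanged", {
  n <- 4000
  X <- rbind(withr::with_seed(8, runif(n, -1, 1)),
             sin(2 * pi * 7 * seq_len(n) / 500),
             2 * ((seq_len(n) / 300) %% 1) - 1)
  ica <- fastica(X, nComponents = 3, seed = 2)
  cors <- abs(cor(t(ica@sources), t(X)))
  expect_true(all(apply(cors, 2, max) >= 0.999))
})

test_that("blink- and line-dominated components are both flagged", {
  rec <- generateRecording(dominantProfile("delta", 0.2), 20, 256, 4,
                           seed = childSeed(100, 2))
  dirty <- injectArtifacts(rec, artifactSpec(12, 100, 50, 10), seed = 502)
  n <- ncol(recordingData(rec))
  line <- 10 * sin(2 * pi * 50 * (seq_len(n) - 1) / 256)
  blink <- (recordingData(dirty) - recordingData(rec))[1, ] - line
  ica <- flagArtifactComponents(fastica(recordingData(dirty), seed = 1), dirty)
  S <- ica@sources
  expect_true(ica@componentFlags[which.max(abs(cor(t(S), blink)))])
  expect_true(ica@componentFlags[which.max(abs(cor(t(S), line)))])
})

test_that("artifact-free recordings are rarely flagged; infinite thresholds never", {
  clean <- 0
  for (s in 1:20) {
    rec <- generateRecording(dominantProfile("alpha", 0.5), 12, 256, 4,
                             seed = childSeed(55, s))
    ## occasional non-convergence on clean near-rank-2 data is expected
    ica <- suppressWarnings(
      flagArtifactComponents(fastica(recordingData(rec), seed = 1), rec))
    clean <- clean + !any(ica@componentFlags)
    if (s <= 3) {
      none <- flagArtifactComponents(fastica(recordingData(rec), seed = 1),
                                     rec, kurtosisZ = Inf, lineRatio = Inf)
      expect_false(any(none@componentFlags))
    }
  }
  expect_gte(clean, 18)
})

test_that("denoising strips injected line power and keeps the shape", {
  rec <- generateRecording(dominantProfile("delta", 0.2), 20, 256, 4,
                           seed = childSeed(100, 2))
  dirty <- injectArtifacts(rec, artifactSpec(0, 0, 50, 10), seed = 502)
  clean <- denoiseRecording(dirty, seed = 3)
  before <- sum(vapply(1:4, function(c)
    oracleBandMass(recordingData(dirty)[c, ], 256, 49.5, 50.5), 0))
  after <- sum(vapply(1:4, function(c)
    oracleBandMass(recordingData(clean)[c, ], 256, 49.5, 50.5), 0))
  expect_lte(after, 0.1 * before)
  expect_identical(dim(recordingData(clean)), dim(recordingData(dirty)))
  expect_equal(samplingRate(clean), samplingRate(dirty))
})

test_that("denoising distorts artifact-free recordings only mildly and is idempotent-ish", {
  for (s in 1:3) {
    rec <- generateRecording(dominantProfile("alpha", 0.5), 12, 256, 4,
                             seed = childSeed(60, s))
    out <- denoiseRecording(rec, seed = 2)
    r <- vapply(1:4, function(c)
      cor(recordingData(out)[c, ], recordingData(rec)[c, ]), 0)
    expect_true(all(abs(r) >= 0.95))
    twice <- denoiseRecording(out, seed = 2)
    rel <- rmsd(recordingData(twice), recordingData(out)) /
      sqrt(mean(recordingData(out)^2))
    expect_lt(rel, 0.10)
  }
})

test_that("single-channel recordings skip the ICA stage with a warning", {
  rec <- generateRecording(dominantProfile("alpha", 0.5), 8, 256, 1, seed = 9)
  expect_warning(out <- denoiseRecording(rec, seed = 1), "single-channel")
  expect_identical(dim(recordingData(out)), dim(recordingData(rec)))
})

test_that("epoch segmentation yields the expected window counts", {
  rec <- generateRecording(dominantProfile("alpha"), 60, 256, 2, seed = 13)
  ep0 <- segmentEpochs(list(rec), epochS = 4, overlap = 0)
  expect_identical(dim(epochArray(ep0)), c(15L, 2L, 1024L))
  ep5 <- segmentEpochs(list(rec), epochS = 4, overlap = 0.5)
  expect_identical(dim(epochArray(ep5))[1], 29L)
  ## non-overlapping epochs tile the recording exactly
  tiled <- do.call(cbind, lapply(1:15, function(i) epochArray(ep0)[i, , ]))
  expect_identical(tiled, recordingData(rec)[, 1:(15 * 1024)])
  expect_true(all(epochLabels(ep0) == conditionId(rec)))
  expect_true(all(epochSubjects(ep0) == subjectId(rec)))
})

test_that("recordings shorter than one epoch are skipped with a warning", {
  rec <- generateRecording(dominantProfile("alpha"), 4, 256, 1, seed = 14)
  long <- generateRecording(dominantProfile("alpha"), 8, 256, 1, seed = 15)
  expect_warning(ep <- segmentEpochs(list(rec, long), epochS = 6), "skipped")
  expect_identical(dim(epochArray(ep))[1], 1L)
})
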