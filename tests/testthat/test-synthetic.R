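test_that("generated recordings have the requested geometry and are seeded", {
  p <- singleBandProfile("alpha", regularity = 1)
  rec <- generateRecording(p, durationS = 4, fs = 256, nChannels = 1, seed = 1)
  expect_identical(dim(recordingData(rec)), c(1L, 1024L))
  expect_equal(samplingRate(rec), 256)

  rec2 <- generateRecording(p, durationS = 4, fs = 256, nChannels = 1, seed = 1)
  expect_identical(recordingData(rec), recordingData(rec2))
  rec3 <- generateRecording(p, durationS = 4, fs = 256, nChannels = 1, seed = 2)
  expect_false(identical(recordingData(rec), recordingData(rec3)))
})

test_that("a pure-alpha profile concentrates its periodogram mass in 8-13 Hz", {
  p <- singleBandProfile("alpha", regularity = 1)
  rec <- generateRecording(p, 8, 256, 1, seed = 1)
  x <- recordingData(rec)[1, ]
  ratio <- oracleBandMass(x, 256, 8, 13) / oracleBandMass(x, 256, 0.5, 45)
  expect_gte(ratio, 0.95)
})

test_that("invalid profiles and geometries are rejected", {
  expect_error(conditionProfile(0L, c(delta = 1, sigma = 1)), "unknown rhythm")
  expect_error(conditionProfile(0L, c(delta = 0, theta = 0, alpha = 0,
                                      beta = 0, gamma = 0)), "not all zero")
  p <- singleBandProfile("gamma")
  expect_error(generateRecording(p, 4, 80, 1, seed = 1), "fs")
})

test_that("empirical band-power fractions track the profile weights", {
  w <- c(delta = .3, theta = .25, alpha = .2, beta = .15, gamma = .1)
  bands <- rhythmBands()
  for (s in 1:3) {
    rec <- generateRecording(conditionProfile(1L, w, 0.4), 60, 256, 2,
                             seed = s)
    X <- recordingData(rec)
    fr <- vapply(names(bands), function(b)
      sum(vapply(seq_len(nrow(X)), function(ch)
        oracleBandMass(X[ch, ], 256, bands[[b]][1], bands[[b]][2]), 0)), 0)
    fr <- fr / sum(fr)
    expect_lt(max(abs(fr - w / sum(w))), 0.05)
  }
})

test_that("higher regularity lowers the sliding sample entropy", {
  wins <- sum(vapply(1:10, function(s) {
    hi <- generateRecording(dominantProfile("beta", 0.9), 4, 256, 1,
                            seed = childSeed(7, s))
    lo <- generateRecording(dominantProfile("beta", 0.1), 4, 256, 1,
                            seed = childSeed(7, s))
    mean(slidingSampleEntropy(recordingData(hi)[1, ])) <
      mean(slidingSampleEntropy(recordingData(lo)[1, ]))
  }, TRUE))
  expect_gte(wins, 10 * 0.95)
})

test_that("zero-amplitude artifact specs leave the recording untouched", {
  rec <- generateRecording(dominantProfile("alpha"), 4, 256, 2, seed = 3)
  out <- injectArtifacts(rec, artifactSpec(0, 0, 50, 0), seed = 1)
  expect_identical(recordingData(out), recordingData(rec))
})

test_that("line injection concentrates the difference signal at the line frequency", {
  rec <- generateRecording(dominantProfile("alpha"), 8, 256, 2, seed = 4)
  out <- injectArtifacts(rec, artifactSpec(0, 0, 50, 10), seed = 1)
  d <- recordingData(out)[1, ] - recordingData(rec)[1, ]
  frac <- oracleBandMass(d, 256, 49.5, 50.5) / oracleBandMass(d, 256, 0, 128)
  expect_gte(frac, 0.99)
})

test_that("blink count is the seeded Poisson draw, recomputable from the seed", {
  rec <- generateRecording(dominantProfile("alpha"), 60, 256, 4, seed = 5)
  out <- injectArtifacts(rec, artifactSpec(12, 100, 50, 0), seed = 99)
  train <- (recordingData(out) - recordingData(rec))[1, ]
  ## each blink adds one raised-cosine bump of 0.3 s and peak 100 uV, so
  ## the injected mass counts the events even when bumps overlap
  bump <- 0.5 * (1 - cos(2 * pi * seq_len(round(0.3 * 256)) /
                           (round(0.3 * 256) + 1))) * 100
  expected <- local({ set.seed(99L); rpois(1, 12 * 1) })
  expect_equal(sum(train) / sum(bump), expected, tolerance = 1e-9)
  out2 <- injectArtifacts(rec, artifactSpec(12, 100, 50, 0), seed = 99)
  expect_identical(recordingData(out), recordingData(out2))
})

test_that("nyquist-violating line frequencies are rejected", {
  rec <- generateRecording(dominantProfile("alpha"), 4, 256, 1, seed = 1)
  expect_error(injectArtifacts(rec, artifactSpec(0, 0, 130, 5), seed = 1),
               "Nyquist")
})

test_that("cohorts have one labelled recording per subject and condition", {
  cohort <- generateCohort(3, defaultProfiles(), durationS = 4, fs = 256,
                           nChannels = 2, seed = 11)
  expect_length(cohort, 15)
  conds <- vapply(cohort, conditionId, 0L)
  subjects <- vapply(cohort, subjectId, "")
  expect_equal(unname(table(conds)), rep(3L, 5), ignore_attr = TRUE)
  expect_length(unique(subjects), 3)
  expect_true(all(table(subjects) == 5))

  cohort2 <- generateCohort(3, defaultProfiles(), durationS = 4, fs = 256,
                            nChannels = 2, seed = 11)
  expect_identical(lapply(cohort, recordingData),
                   lapply(cohort2, recordingData))
  cohort3 <- generateCohort(3, defaultProfiles(), durationS = 4, fs = 256,
                            nChannels = 2, seed = 12)
  expect_false(identical(recordingData(cohort[[1]]),
                         recordingData(cohort3[[1]])))
})

test_that("duplicate condition ids in a cohort spec are rejected", {
  profs <- defaultProfiles()[c(1, 1)]
  expect_error(generateCohort(2, profs, 4, 256, 1, seed = 1), "duplicate")
})
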