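## Synthetic multi-channel EEG with class-specific rhythm power and
## regularity. Every stochastic quantity flows from an explicit seed.

## Band-limited white noise: unit-variance white noise, boxcar-filtered to
## [lo, hi) Hz on the FFT grid of the requested length. Exactly in-band.
bandNoise <- function(n, fs, lo, hi) {
  w <- rnorm(n)
  W <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  W[!(f >= lo & f < hi)] <- 0 + 0i
  Re(fft(W, inverse = TRUE)) / n
}

## Fixed tone frequency per rhythm band. The tones are harmonics of a
## common 2 Hz fundamental (cross-frequency phase coupling, as nested EEG
## rhythms show), so the deterministic part of a multi-band signal is
## periodic and template-matching entropy can see its regularity.
bandToneHz <- c(delta = 2, theta = 6, alpha = 10, beta = 20, gamma = 36)

## Phase-jittered sinusoid at the band tone: a random-walk phase whose
## step keeps the Lorentzian linewidth near 0.2% of the band width, so the
## line stays well inside its band and stays coherent over entropy
## windows while never being exactly periodic.
jitteredSine <- function(n, fs, lo, hi, f0) {
  sigma <- sqrt(2 * pi * 0.002 * (hi - lo) / fs)
  phase <- 2 * pi * f0 * (seq_len(n) - 1) / fs +
    cumsum(rnorm(n, sd = sigma)) + runif(1, 0, 2 * pi)
  sin(phase)
}

unitRMS <- function(x) {
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

#' Generate one synthetic EEG recording
#'
#' The signal is a sum over the five rhythm bands of band-limited
#' processes. Within a band, the amplitude fraction `regularity` comes
#' from a phase-jittered sinusoid at the band's tone frequency (harmonics
#' of a common 2 Hz fundamental: 2, 6, 10, 20, 36 Hz) and the fraction
#' `1 - regularity` from boxcar band-passed white noise; each band's mix
#' is renormalized so the long-run band power fractions equal `bandPower`
#' normalized to 1. The whole recording is scaled to `rmsUv` microvolts
#' RMS.
#'
#' Channels observe the band sources through two spatial gain patterns
#' drawn per recording (slow bands delta/alpha/gamma share one pattern,
#' theta/beta the other), as volume conduction spreads a cortical source
#' across electrodes; gains vary in magnitude and sign, as dipolar sources
#' do across the scalp, and each pattern is normalized to equal total
#' power so the pooled band-power fractions stay exactly at `bandPower`.
#' A small per-channel sensor-noise floor (`sensorNoise` fraction of the
#' signal power, band-limited to the rhythm range) keeps the channel
#' covariance well conditioned.
#'
#' @param profile a [ConditionProfile-class].
#' @param durationS duration in seconds (>= 4).
#' @param fs sampling rate in Hz (>= 100).
#' @param nChannels number of channels (>= 1).
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @param subjectId subject identifier carried on the recording.
#' @param rmsUv per-channel RMS amplitude in microvolts.
#' @param sensorNoise per-channel independent noise power as a fraction of
#'   the shared-signal power (default 0.01).
#' @param bands rhythm band edges, see [rhythmBands()].
#' @return an [EEGRecording-class].
#' @examples
#' p <- conditionProfile(2L, c(delta = 0, theta = 0, alpha = 1,
#'                             beta = 0, gamma = 0), regularity = 1)
#' rec <- generateRecording(p, durationS = 4, fs = 256, nChannels = 1,
#'                          seed = 1)
#' dim(recordingData(rec))   # 1 x 1024
#' @export
generateRecording <- function(profile, durationS, fs, nChannels,
                              seed, subjectId = "S1", rmsUv = 20,
                              sensorNoise = 0.01, bands = rhythmBands()) {
  stopifnot(is(profile, "ConditionProfile"))
  validObject(profile)
  validateBands(bands)
  if (durationS < 4) stop("durationS must be >= 4 s", call. = FALSE)
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  if (fs <= 2 * maxBandEdge(bands))
    stop(sprintf("fs = %g too low for the gamma band (need > %g Hz)",
                 fs, 2 * maxBandEdge(bands)), call. = FALSE)
  if (nChannels < 1) stop("nChannels must be >= 1", call. = FALSE)

  n <- round(durationS * fs)
  w <- profile@bandPower / sum(profile@bandPower)
  rho <- profile@regularity

  pattern <- c(delta = 1, theta = 2, alpha = 1, beta = 2, gamma = 1)
  data <- withLocalSeed(seed, {
    drawPattern <- function() {
      g <- runif(nChannels, 0.5, 1.5) * sample(c(-1, 1), nChannels, TRUE)
      g / sqrt(sum(g^2)) * sqrt(nChannels)   # equal total power
    }
    G <- list(drawPattern(), drawPattern())
    shared <- matrix(0, nChannels, n)
    for (b in rhythmNames()) {
      if (w[[b]] == 0) next
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      f0 <- if (bandToneHz[[b]] >= lo && bandToneHz[[b]] < hi)
        bandToneHz[[b]] else (lo + hi) / 2
      comp <- rho * unitRMS(jitteredSine(n, fs, lo, hi, f0)) +
        (1 - rho) * unitRMS(bandNoise(n, fs, lo, hi))
      shared <- shared + sqrt(w[[b]]) * outer(G[[pattern[[b]]]], unitRMS(comp))
    }
    if (sensorNoise > 0) {
      lo <- min(vapply(bands, `[`, 0, 1)); hi <- maxBandEdge(bands)
      noise <- t(vapply(seq_len(nChannels), function(ch)
        unitRMS(bandNoise(n, fs, lo, hi)), numeric(n)))
      shared <- shared + sqrt(sensorNoise) * noise
    }
    shared
  })
  data <- data * (rmsUv / max(sqrt(mean(data^2)), .Machine$double.eps))
  eegRecording(data, fs, subjectId = subjectId,
               conditionId = profile@conditionId)
}

## Smooth unipolar blink bump (raised-cosine, `widthS` seconds wide).
blinkBump <- function(widthS, fs) {
  m <- round(widthS * fs)
  0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
}

#' Inject ocular and mains artifacts into a recording
#'
#' Adds blink transients (smooth unipolar bumps about 0.3 s wide, arriving
#' as a Poisson process at `blinkRate` per minute, scaled per channel by a
#' fixed frontal-weighted topography cycling over `c(1, 0.8, 0.3, 0.1)`) and
#' a mains sinusoid at `lineFreq` on all channels. The input is not
#' modified.
#'
#' @param rec an [EEGRecording-class].
#' @param spec an [ArtifactSpec-class].
#' @param seed integer seed for blink timing.
#' @return a contaminated copy of `rec`.
#' @export
injectArtifacts <- function(rec, spec, seed) {
  stopifnot(is(rec, "EEGRecording"), is(spec, "ArtifactSpec"))
  validObject(rec); validObject(spec)
  if (spec@lineAmplitude > 0 && spec@lineFreq >= rec@fs / 2)
    stop("lineFreq must be below the Nyquist frequency fs/2", call. = FALSE)

  data <- rec@data
  n <- ncol(data); fs <- rec@fs
  topo <- rep_len(c(1, 0.8, 0.3, 0.1), nrow(data))

  if (spec@blinkRate > 0 && spec@blinkAmplitude > 0) {
    blink <- withLocalSeed(seed, {
      durationMin <- n / fs / 60
      k <- rpois(1, spec@blinkRate * durationMin)
      train <- numeric(n)
      if (k > 0) {
        bump <- blinkBump(0.3, fs) * spec@blinkAmplitude
        starts <- sort(ceiling(runif(k, 0, n - length(bump))))
        for (s in starts) {
          idx <- s + seq_along(bump) - 1L
          train[idx] <- train[idx] + bump
        }
      }
      train
    })
    data <- data + outer(topo, blink)
  }

  if (spec@lineAmplitude > 0) {
    line <- spec@lineAmplitude *
      sin(2 * pi * spec@lineFreq * (seq_len(n) - 1) / fs)
    data <- data + matrix(line, nrow = nrow(data), ncol = n, byrow = TRUE)
  }

  initialize(rec, data = data)
}

#' Generate a labelled cohort of recordings
#'
#' One recording per subject per condition profile. Each subject gets a
#' deterministic child seed (see [childSeed()]) and a random overall gain in
#' +-20% emulating inter-subject amplitude variability.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param profiles list of [ConditionProfile-class] with unique condition
#'   ids; defaults to [defaultProfiles()].
#' @param durationS,fs,nChannels recording geometry, see
#'   [generateRecording()].
#' @param artifacts an [ArtifactSpec-class]; pass amplitudes of 0 for clean
#'   recordings.
#' @param seed master seed.
#' @return a list of `nSubjects * length(profiles)` [EEGRecording-class]
#'   objects, ordered subject-major.
#' @examples
#' cohort <- generateCohort(2, defaultProfiles(), durationS = 4, fs = 256,
#'                          nChannels = 2,
#'                          artifacts = artifactSpec(0, 0, 50, 0), seed = 1)
#' length(cohort)    # 10
#' @export
generateCohort <- function(nSubjects, profiles = defaultProfiles(),
                           durationS = 60, fs = 256, nChannels = 4,
                           artifacts = artifactSpec(0, 0, 50, 0),
                           seed = 1L) {
  if (nSubjects < 1) stop("nSubjects must be >= 1", call. = FALSE)
  if (!length(profiles)) stop("profiles must be non-empty", call. = FALSE)
  ids <- vapply(profiles, function(p) p@conditionId, 0L)
  if (anyDuplicated(ids))
    stop("duplicate condition ids in profiles", call. = FALSE)

  recs <- vector("list", nSubjects * length(profiles))
  k <- 0L
  for (s in seq_len(nSubjects)) {
    sid <- sprintf("S%02d", s)
    gain <- withLocalSeed(childSeed(seed, s), runif(1, 0.8, 1.2))
    for (j in seq_along(profiles)) {
      k <- k + 1L
      recSeed <- childSeed(seed, s * 1000L + j)
      rec <- generateRecording(profiles[[j]], durationS, fs, nChannels,
                               seed = recSeed, subjectId = sid,
                               rmsUv = 20 * gain)
      recs[[k]] <- injectArtifacts(rec, artifacts,
                                   seed = childSeed(seed, s * 1000L + j + 500L))
    }
  }
  recs
}

#' Default five-condition profiles
#'
#' The simulated study design: a no-music condition plus four music styles.
#' Each condition is dominated by a distinct rhythm (weight 0.6 against 0.1
#' for the others) and the conditions span regularities 0.2 to 0.8, so the
#' classes differ both in band power and in sample entropy.
#'
#' @return list of five [ConditionProfile-class] objects (condition ids
#'   0-4).
#' @export
defaultProfiles <- function() {
  dom <- function(b) {
    w <- c(delta = .1, theta = .1, alpha = .1, beta = .1, gamma = .1)
    w[b] <- 0.6
    w
  }
  list(
    conditionProfile(0L, dom("delta"), regularity = 0.20),
    conditionProfile(1L, dom("theta"), regularity = 0.35),
    conditionProfile(2L, dom("alpha"), regularity = 0.50),
    conditionProfile(3L, dom("beta"),  regularity = 0.65),
    conditionProfile(4L, dom("gamma"), regularity = 0.80)
  )
}
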