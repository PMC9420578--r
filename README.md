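# museeg

Classification of multi-channel EEG recorded under different music
listening conditions — a no-music baseline plus four music styles — built
for researchers who want every stage of such a pipeline available,
seeded, and testable without access to patient data.

The package provides:

* a **synthetic-EEG generator** with per-condition rhythm power profiles
  (δ/θ/α/β/γ), a regularity parameter controlling oscillation-vs-noise
  mix, and injectable ocular (blink) and mains (50 Hz) artifacts;
* **denoising** by FastICA artifact-component rejection (kurtosis and
  line-frequency criteria) followed by empirical mode decomposition with
  Hilbert instantaneous-frequency screening;
* **features**: frequency band energy ratios from a harmonic wavelet
  packet transform, and sliding-average sample entropy — 25 values of
  each per epoch, 50 columns total;
* a **deep belief network** classifier: stacked restricted Boltzmann
  machines pretrained with contrastive divergence (CD-1), a softmax head,
  and gradient-descent fine-tuning with an MSE trace;
* **reporting**: row-normalized confusion matrix, per-subject accuracy
  summary, MSE-per-iteration trace, and per-band t-test comparisons.

## The model in brief

For each rhythm band *p* the harmonic wavelet packet transform yields
complex coefficients *hwpt(s, i, k)*; the band energy and its ratio are

```
E_p = Σ_k Σ_i |hwpt(s, i, k)|²,   FBER_p = E_p / Σ_p E_p × 100%
```

Sample entropy is the Richman–Moorman statistic `−ln(A/B)` (template
length m = 2, tolerance r = 0.2·SD, Chebyshev distance, self-matches
excluded). The classifier stacks RBMs `P(x, g¹, …, gˡ) =
P(x|g¹)P(g¹|g²)⋯` trained greedily by CD-1, with a softmax head
`p(y = j|x) = exp(θ_jᵀx)/Σ_i exp(θ_iᵀx)` fine-tuned by backpropagation.

## Worked example

```r
library(museeg)

profiles <- defaultProfiles()            # five conditions, 0 = no music
rec <- generateRecording(profiles[[3]], durationS = 8, fs = 256,
                         nChannels = 4, seed = 1)
rec
#> EEGRecording: 4 channel(s) x 2048 samples @ 256 Hz (8.0 s)
#>   subject S1, condition 2

round(colMeans(t(sapply(1:4, function(ch)
  fber(recordingData(rec)[ch, ], 256)))), 2)
#> delta theta alpha  beta gamma
#>  9.72 11.12 57.39 11.58 10.18
```

Condition 2 is generated α-dominant (weight 0.6 against 0.1 per other
band) and the channel-averaged FBER recovers that: ~57 % of rhythm energy
in 8–13 Hz, the rest spread evenly. A reduced end-to-end run (8 subjects
instead of the default 28):

```r
cfg <- defaultPipelineConfig(seed = 7)
cfg$cohort$nSubjects <- 8L
cfg$cohort$durationS <- 36
report <- runPipeline(cfg)
report
#> ClassificationReport
#>   test accuracy: 100.00%
#>   subject accuracy mean 100.00 / min 100.00 / max 100.00 %
#>   confusion (%):
#>     predicted
#> true   0   1   2   3   4
#>    0 100   0   0   0   0
#>    1   0 100   0   0   0
#>    2   0   0 100   0   0
#>    3   0   0   0 100   0
#>    4   0   0   0   0 100
```

The five conditions are well separated by construction (each dominated by
a distinct rhythm, regularity spread 0.2–0.8), so a correct pipeline
recovers them essentially perfectly; the interesting failures show up
when you narrow the profiles or shrink the cohort yourself.

A command-line wrapper with `simulate | denoise | epoch | features |
train | predict | run-all` subcommands is installed at
`inst/scripts/museeg-cli.R`.

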