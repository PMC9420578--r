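Package: museeg
Title: Music-Perception EEG Classification with Band-Energy and Entropy
    Features and a Deep Belief Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation, preprocessing, feature extraction and
    classification of multi-channel EEG recorded under different music
    listening conditions. Provides a seeded synthetic-EEG generator with
    class-specific rhythm (delta/theta/alpha/beta/gamma) power profiles
    and regularity, ocular and mains artifact injection, denoising by
    empirical mode decomposition with Hilbert instantaneous-frequency
    screening followed by FastICA artifact-component rejection, harmonic
    wavelet packet band-energy ratio (FBER) and sliding-average sample
    entropy features, and a deep belief network (stacked restricted
    Boltzmann machines pretrained by contrastive divergence, softmax head
    fine-tuned by gradient descent) with confusion-matrix and per-subject
    accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
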