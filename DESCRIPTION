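Package: songlfp
Title: Local Field Potential Analysis of Zebra Finch Song
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing multichannel local field potential (LFP)
    recordings from the songbird premotor nucleus HVC during singing:
    annotation handling (Praat TextGrid I/O, vocally-active-period grouping,
    bout/motif context labels, class balancing), signal conditioning
    (FIR low-pass decimation, common average referencing, a log-spaced
    Hilbert filterbank), spectral characterisation (VAP-normalised
    spectrograms, cross-trial z-scores, multitaper power spectra and
    principal spectral components, sensitivity indices with permutation
    nulls), inter-trial phase coherence with Rayleigh statistics and the
    normalised sustained Z profile, template-based LDA decoding of syllable
    identity with channel-adding bootstrap curves, and template-matching
    prediction of syllable onset times against a stereotyped-behaviour
    baseline.  A seeded synthetic songbird generator (song grammar plus
    phase-locked multichannel LFP) provides a ground-truth test bed for
    every stage.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
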