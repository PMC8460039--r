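---
title: "Analysing songbird LFP during singing: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing songbird LFP during singing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songlfp)
```

## The scientific setting

Adult male zebra finches sing a stereotyped *motif* — a fixed sequence of
syllables — repeated in *bouts*, optionally preceded by introductory
notes and sometimes extended with intra-motif "connector" notes at the
motif boundary.  Extracellular electrodes in the premotor nucleus HVC
record local field potentials (LFP) whose spectral power and oscillatory
phase carry information about this behavior.  `songlfp` implements the
full analysis chain for such recordings:

1. **Annotations** — Praat TextGrid I/O, grouping of motifs into
   vocally active periods (VAPs; motifs separated by at most 20 s share
   a VAP), bout/motif context labels, and class balancing.
2. **Signal conditioning** — 400 Hz FIR low-pass + decimation to
   1 kHz with group-delay compensation, common average referencing, and
   a 100-band log-spaced Hilbert filterbank (2–200 Hz).
3. **Spectral characterisation** — VAP-normalised spectrograms,
   cross-trial z-scores, multitaper PSDs (1 s windows, 14 Slepian
   tapers), principal spectral components (PSCs), cosine similarity,
   and d′ sensitivity with a label-shuffle permutation null.
4. **Phase locking** — inter-trial phase coherence (ITPC), the
   Rayleigh Z statistic and its asymptotic p-value, significance
   masking at Z > 5, the normalised sustained-Z profile, and
   syllable-aligned vs stereotyped-time contrasts.
5. **Decoding** — band templates, Pearson-correlation features, LDA
   with equal priors and 5-fold stratified cross-validation, a
   bin-width/offset hyperparameter search, phase-only/power-only
   ablations, and channel-adding bootstrap curves.
6. **Onset prediction** — sliding template-matching confidence traces,
   a 100 ms decision window centered on the stereotyped onset time, a
   behavioral baseline, Wilcoxon/BH evaluation, and the branch-point
   (omitted-syllable) Welch analysis.

Because no public recordings accompany this problem, the package ships
a first-class synthetic generator (`song_grammar()`,
`sample_behavior()`, `lfp_model()`, `synthesize_lfp()`) whose
construction realises exactly the statistical structure the analyses
assume.  Every stage is validated against that ground truth.

## Key statistics

**ITPC.**  For trial phases $\varphi_k(f,t)$ the inter-trial phase
coherence is the resultant length
$r(f,t) = \left|\tfrac1n\sum_k e^{i\varphi_k(f,t)}\right|$, computed
independently at every (frequency, time) point.  $r=0$ is the uniform
null, $r=1$ perfect synchrony.

**Rayleigh statistic.**  $Z = n r^2$ (equivalently $R^2/n$ with
$R = nr$), with the asymptotic p-value
$$P = \exp\!\big(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n)\big),$$
clipped to $(0,1]$.  At $r=0$ the argument collapses exactly
($1+4n+4n^2=(1+2n)^2$) and $P=1$.  The square root is essential: the
same expression without it does not reproduce the standard bounds
(e.g. $P \le 0.006$ at $Z=5$, $n=27$; $P \le 0.007$ at $Z=5$, $n=98$),
which the test suite asserts and a uniform-phase Monte-Carlo confirms.

**Cross-trial z-score.**  Per frequency, every trial spectrogram is
centred by the grand mean over time and trials; the across-trial mean
at each (f, t) is divided by the across-trial SD.  Values around ±2
bound an approximate 95% interval.  Zero-variance points are returned
as flagged zeros rather than NaN.

**PSCs.**  Multitaper PSDs of balanced vocally-active and inactive
1 s windows are divided by the ensemble mean per frequency and logged;
the between-frequency covariance (the raw cross-product over trials —
deliberately not divided by the trial count, since eigenvectors are
scale invariant) is eigen-decomposed.  Eigenvectors are the principal
spectral components; trial projections onto them separate behavioral
states, quantified by
$d' = |\mu_a-\mu_i|/\sqrt{(\sigma_a^2+\sigma_i^2)/2}$ with a
label-shuffle permutation p-value using the $(b+1)/(m+1)$ estimator.

**Decoding features.**  For each class a template is the mean training
trace in the window $[{\rm onset}-{\rm offset}-{\rm bin},\,
{\rm onset}-{\rm offset})$; a feature is the Pearson correlation of an
event's own window with each class template, per channel.  All windows
precede the onset and all decoding traces come from causal (forward
only) filters, so no feature can see the event itself.

## The synthetic generator

`sample_behavior()` draws bouts from a small stochastic grammar: a
5-syllable motif (durations 70–100 ms), silent gaps of 100 ms, 0–3
introductory notes, a branch point at every motif boundary (insert a
connector note / continue / end the bout, default 0.5/0.2/0.3, with an
extra 40 ms latency before connectors), occasional calls, and
inter-bout silences of at least 3 s.  Motif timing is clock-anchored:
each element's onset jitters *independently* (SD 15 ms) around the
stereotyped schedule rather than accumulating gap-by-gap, matching the
tight tempo regulation of zebra finch motifs — with random-walk
accumulation the fifth element would drift ~35 ms against the motif
anchor, which real birds do not do.  Two silence labels are carried:
`"gap"` within song and `"silence"` elsewhere in the VAP.

`synthesize_lfp()` adds, on top of $1/f$ Gaussian background noise
(partially shared across channels):

* **Band transients** — for each of the five canonical bands (4–8,
  8–12, 25–35, 35–50, 50–70 Hz), a Gaussian-envelope (Morlet-style)
  burst at the band's geometric centre frequency, centred on every
  vocal onset, with SD of about two carrier cycles (at most 55 ms;
  widened to $800/f_c$ ms at low frequencies).  The burst's phase *at
  the onset sample* is drawn von Mises around the event class's
  preferred phase with concentration $\kappa = 24$ ($\kappa=\infty$
  gives an exact reset).  Two properties of this construction were
  verified and are worth stating because they constrain any such
  generator: (i) the Gaussian envelope is compact in time and frequency
  at once, so adjacent bands and adjacent syllables leak only a few
  percent into one another; and (ii) the envelope must *peak at* the
  measurement sample — phase read off a burst at a time away from its
  envelope peak, through a band filter that truncates the burst
  spectrum asymmetrically, acquires a bias proportional to the offset
  (about 0.1 rad at 30 ms in the 35–50 Hz band).  With the centred
  envelope the programmed preferred phases are recoverable to better
  than 0.1 rad in the 25–70 Hz bands.  At 4–12 Hz one oscillation
  cycle exceeds the syllable spacing, so syllable-resolved phase
  recovery is physically impossible there — the low bands are
  validated through the sustained-Z profile instead.
* **Anticipatory class templates** — a fixed broadband waveform per
  class (SNR 1.8 relative to the background; doubled for the optional
  connector note) in the window 140–70 ms *before* the onset, with
  spectral content stratified so that every analysis band holds
  several components (the five analysis-band strata at half weight).
  This is the premotor signature that the causal decoders and the
  onset predictor read.  Three geometric constraints shaped it, each
  verified by construction experiments: the window must end well
  before the onset *and* start after the preceding element's onset
  (otherwise the zero-phase filters smear its fixed-phase content onto
  an onset sample and bias the measured preferred phases); the
  locked-band strata must be present in every band (sparse random
  content leaves some band cycle-ambiguous for the matched filter) but
  weighted low enough not to dominate the phase measurement; and the
  signature must be strong overall, because it competes inside the
  feature windows with the jittering tails of neighbouring syllables'
  bursts.  A slow class-specific Gaussian amplitude modulation
  (depth 0.5, widths 50–100 ms) of each burst additionally separates
  classes from amplitude alone.
* **Why anticipation is explicit** — decoding features must come from
  causal filters and windows that fully precede the onset.  A causal
  band-pass delays its output by roughly the inverse bandwidth
  (~94 ms at 25–35 Hz, ~44 ms at 50–70 Hz), so energy centred *at*
  the onset arrives in the filtered trace after it: a generator whose
  only event-locked structure sits at the onset leaves nothing for a
  pre-onset window to match, and the template correlation then drifts
  toward whichever window has the most signal energy.  The dedicated
  pre-onset signature resolves this, and mirrors the premotor nature
  of HVC, where activity leads the vocal gesture.
* **High gamma** — the > 50 Hz part of the background is multiplied by
  `highgamma_gain` (default 2) during vocal intervals.
* **Channel structure** — channels receive alternating-polarity gains
  (laminar inversion); without this, common-average referencing would
  cancel the event-locked signal entirely.

What the generator does *not* emulate: spiking contamination, movement
artifacts, electrode drift, 50/60 Hz mains, non-stationary background
statistics, or realistic acoustics (the WAV writer emits schematic
tones only).  Passing tests therefore demonstrate the correctness and
calibration of the analysis chain, not its robustness to every
real-world nuisance.

## Numerical and design choices

* **Narrowband filters** are 4th-order Butterworth band-passes designed
  in zero-pole-gain form and run as cascaded biquads (second-order
  sections): full-polynomial coefficients are numerically unstable at
  the ~5% fractional bandwidths of the 100-band bank.  Zero-phase
  analyses use forward-backward application with 1 s odd-reflection
  padding; decoding uses forward-only (causal) application.
* **Band layout**: 100 geometrically spaced centres over 2–200 Hz,
  each band's half-power width equal to the log step so adjacent bands
  overlap at half power.
* **Hilbert transform** via FFT with 1 s reflection padding, extended
  to 2-3-5-smooth lengths (an FFT at an awkward prime-ish length is
  orders of magnitude slower).
* **Multitaper**: NW = 7.5 so that exactly 14 tapers are
  well-concentrated in a 1 s window; DPSS computed from the standard
  symmetric tridiagonal eigenproblem.
* **Sustained Z**: the mean Z over the one-cycle span (at the band's
  geometric centre) immediately preceding the alignment sample,
  normalised by the maximum Z.  Both normalisations are available;
  per-frequency is the default, but for comparisons *across* bands the
  global maximum is the discriminative choice — with per-frequency
  normalisation the strong autocorrelation of narrowband Z traces
  drives mean/max toward 1 everywhere on short epochs.
* **Degenerate inputs**: zero cross-trial variance → flagged zeros;
  zero-variance Pearson segments → feature 0; zero pooled variance in
  d′ → capped sentinel; non-finite phases → trial excluded at that
  sample with n adjusted; all argmax ties → earliest sample.
* **Balancing** is seeded, uniform without replacement, to the minimum
  class count; silence pseudo-events are centred in silent spans of at
  least 2 s.
* **VAP grouping** treats the 20 s threshold inclusively and pads VAPs
  by 2 s (the padding before the first and after the last motif is not
  dictated by the problem; it is configurable).
* **Wilcoxon direction** in the alignment contrast: alternative =
  labeled-onset alignment more coherent.  Onset-prediction evaluation
  tests two null hypotheses (no difference; neural not closer) and
  requires both at p < 0.05, with BH at q = 0.05 across the six
  predictors (five bands + all-frequency).
* **The connector class** is deliberately excluded from the balanced
  LDA vocabulary on the default dataset (its count is far below the
  other classes); it is instead the subject of the branch-point
  analysis, where its occurrences and omissions are compared fold-wise
  with one-sided Welch t-tests.
* **The example decoding band** is 50–70 Hz.  Under causal filtering
  each band delays the signal by roughly its inverse bandwidth (about
  94 ms at 25–35 Hz but only 44 ms at 50–70 Hz), so with a fixed
  100 ms/10 ms feature window the higher bands retain the most usable
  pre-onset burst energy.  This is the same reason a per-frequency
  window search (as `hyperparameter_search()` provides) is worthwhile
  on real data.

## Problem sizes

The validation suite and the reproduction script run the full chain on
30 bouts of the default grammar with 16 channels at 1 kHz (about 3–4
minutes of recording), 100-band ITPC on a single channel, balanced
decoding of 7 classes, and 5-fold onset prediction for every non-first
syllable — sizes chosen so the entire suite completes on a laptop-class
single core in well under half an hour while keeping every statistical
test adequately powered.  Null-calibration checks use 400–1000
replicates per condition.

## Known limitations

* The Rayleigh p-value is an asymptotic approximation; for very small
  n (< 10) it is conservative near p = 1 and slightly liberal in the
  far tail.
* Phase recovery at 4–12 Hz against syllable onsets is limited by the
  physics of the construction (cycle length vs syllable spacing), not
  by the estimator.
* The LDA uses MASS's SVD-based solver; with more features than
  events the discriminant directions are regularised only by
  singular-value truncation, mirroring the stated design (no
  shrinkage), so accuracies at very high channel counts are
  conservative rather than inflated.
* `group_vaps()` operates on motif onset times; annotations whose
  motifs are unlabelled must be contextualised first.
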