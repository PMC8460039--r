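# Inter-trial phase coherence and its statistics.

#' Inter-trial phase coherence
#'
#' The resultant length of the mean unit phasor across trials,
#' `r = |mean_k exp(i phi_k)|`, computed independently at every
#' (frequency, time) point.  Non-finite phases are excluded at that
#' point with the trial count adjusted (and flagged).
#'
#' @param phases array of instantaneous phases (radians) with trials on
#'   the first dimension: `[trial]`, `[trial, time]` or
#'   `[trial, band, time]`.
#' @return object of class `itpc_result`: `r`, `mean_angle`, `n`
#'   (effective trial count), `Z = n r^2`, `p` (Rayleigh), `flagged`
#'   (points with excluded trials).  Shapes follow the input minus the
#'   trial dimension.
#' @export
itpc <- function(phases) {
  if (is.null(dim(phases))) phases <- matrix(phases, ncol = 1)
  d <- dim(phases)
  if (d[1] < 2) stop("itpc needs at least 2 trials")
  z <- exp(1i * phases)
  z[!is.finite(phases)] <- NA
  margins <- seq_along(d)[-1]
  n_eff <- apply(!is.na(z), margins, sum)
  mean_z <- apply(z, margins, function(v) mean(v, na.rm = TRUE))
  r <- Mod(mean_z)
  r <- pmin(r, 1)
  ray <- rayleigh(r, n_eff)
  structure(list(r = r, mean_angle = Arg(mean_z), n = n_eff,
                 Z = ray$Z, p = ray$p, flagged = n_eff < d[1]),
            class = "itpc_result")
}

#' Rayleigh Z statistic and p-value
#'
#' `Z = n r^2` (equivalently `R^2 / n` with the Rayleigh `R = n r`).
#' The p-value uses the standard asymptotic approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`, clipped to
#' `(0, 1]`.  At `r = 0` the argument collapses exactly
#' (`1 + 4n + 4n^2 = (1 + 2n)^2`) and `p = 1`.
#'
#' @param r resultant length(s), in `[0, 1]`.
#' @param n trial count(s), `>= 2`.
#' @return list `Z`, `p` (same shape as `r`).
#' @export
rayleigh <- function(r, n) {
  stopifnot(all(r >= 0 & r <= 1e0 + 1e-12))
  Z <- n * r^2
  R2 <- (n * r)^2
  arg <- pmax(1 + 4 * n + 4 * (n^2 - R2), 0)
  p <- exp(sqrt(arg) - (1 + 2 * n))
  p <- pmin(p, 1)
  p <- pmax(p, .Machine$double.xmin)
  if (!is.null(dim(Z))) dim(p) <- dim(Z)
  list(Z = Z, p = p)
}

#' Significance mask at a Rayleigh Z threshold
#'
#' Strictly-greater comparison; in ITPC images the points below
#' threshold are rendered black.
#'
#' @param Z numeric array of Rayleigh Z values.
#' @param z_threshold display threshold (default 5).
#' @return logical array, `TRUE` where `Z > z_threshold`.
#' @export
significance_mask <- function(Z, z_threshold = 5) {
  Z > z_threshold
}

#' ITPC of a recording around aligned events
#'
#' Streams over bands and computes, for one channel, the ITPC of the
#' filterbank phase in a window around each alignment time.  Memory
#' stays at one band's time series, so the full 100-band bank is usable
#' on long recordings.
#'
#' @param rec an `lfp_recording`.
#' @param events alignment sample indices (trials).
#' @param window `c(before, after)` seconds around the alignment time.
#' @param bands band table (`low`, `high`; default the 100-band
#'   log-spaced bank over 2-200 Hz).
#' @param channel channel index.
#' @param causal use causal filtering (default `FALSE`).
#' @return an `itpc_result` with matrices `[band, time]`, plus `bands`,
#'   `time` (seconds relative to alignment) and `fs`.
#' @export
itpc_events <- function(rec, events, window = c(0.2, 0.2), bands = NULL,
                        channel = 1, causal = FALSE) {
  if (is.null(bands)) bands <- filterbank_bands(100, c(2, 200))
  fs <- rec$fs
  nbef <- round(window[1] * fs); naft <- round(window[2] * fs)
  tlen <- nbef + naft + 1L
  nb <- nrow(bands)
  ntr <- length(events)
  if (ntr < 2) stop("need at least 2 trials")
  x <- rec$voltage[channel, ]
  r <- Z <- p <- ang <- matrix(NA_real_, nb, tlen)
  n_eff <- matrix(ntr, nb, tlen)
  for (bi in seq_len(nb)) {
    flt <- butter_bandpass_sos(4, bands$low[bi], bands$high[bi], fs)
    y <- if (causal) sosfilt(flt, x) else sosfiltfilt(flt, x)
    ph <- Arg(analytic_signal(y, fs))
    tr <- matrix(NA_real_, ntr, tlen)
    for (k in seq_len(ntr)) {
      i0 <- round(events[k]) - nbef
      idx <- (i0 + 1L):(i0 + tlen)
      ok <- idx >= 1L & idx <= length(ph)
      tr[k, ok] <- ph[idx[ok]]
    }
    res <- itpc(tr)
    r[bi, ] <- res$r; Z[bi, ] <- res$Z; p[bi, ] <- res$p
    ang[bi, ] <- res$mean_angle; n_eff[bi, ] <- res$n
  }
  structure(list(r = r, mean_angle = ang, n = n_eff, Z = Z, p = p,
                 flagged = n_eff < ntr, bands = bands,
                 time = (seq_len(tlen) - nbef - 1L) / fs, fs = fs),
            class = "itpc_result")
}

#' Normalized sustained Rayleigh Z profile
#'
#' Per frequency band: the mean Rayleigh Z over the samples spanning one
#' oscillation cycle (at the band's geometric-center frequency)
#' immediately preceding the alignment time (exclusive), divided by the
#' maximum Z over the whole analyzed epoch.  By default the maximum is
#' taken per frequency; `global_max = TRUE` normalises by the single
#' maximum across all frequencies (the choice rescales but does not move
#' peaks).
#'
#' @param Z matrix `[band, time]` of Rayleigh Z values.
#' @param bands band table with `low`, `high` (Hz) matching the rows.
#' @param fs sampling rate (Hz).
#' @param onset_col column index of the alignment time (t = 0).
#' @param global_max normalisation mode.
#' @return numeric vector in `[0, 1]`, one value per band.
#' @export
sustained_z <- function(Z, bands, fs, onset_col, global_max = FALSE) {
  nb <- nrow(Z)
  centers <- sqrt(bands$low * bands$high)
  prof <- numeric(nb)
  for (bi in seq_len(nb)) {
    cyc <- max(1L, round(fs / centers[bi]))
    lo <- max(1L, onset_col - cyc)
    hi <- onset_col - 1L
    if (hi < lo) stop("window too short to hold one cycle of band ", bi)
    num <- mean(Z[bi, lo:hi])
    den <- if (global_max) max(Z) else max(Z[bi, ])
    prof[bi] <- if (den > 0) num / den else 0
  }
  pmin(pmax(prof, 0), 1)
}

#' Syllable-aligned vs stereotyped-time ITPC contrast
#'
#' For one syllable class: compares the Rayleigh Z of phases sampled at
#' the labeled onsets against the Z of phases sampled at the syllable's
#' stereotyped time (the training-mean onset relative to the motif's
#' first syllable, applied to each motif's actual first-syllable onset).
#' The Z values at the designated time are concatenated across channels
#' and bands into one vector per alignment; their difference
#' (labeled - stereotyped, positive = more coherent at the labeled
#' onset) is tested with a one-sided Wilcoxon signed-rank test.
#'
#' @param rec an `lfp_recording`.
#' @param onsets labeled onset samples of the syllable instances.
#' @param anchors matching first-syllable onset samples of the containing
#'   motifs.
#' @param bands band table (default the five canonical narrow bands).
#' @param channels channel indices (default good channels).
#' @return list: `difference` (vector over channel x band), `z_labeled`,
#'   `z_stereotyped`, `p` (one-sided Wilcoxon, alternative "greater"),
#'   `stereotyped_offset` (samples).
#' @export
alignment_contrast <- function(rec, onsets, anchors, bands = NULL,
                               channels = which(rec$good_mask)) {
  if (is.null(bands)) {
    cb <- canonical_bands()
    bands <- cb[1:5, c("low", "high")]
  }
  keep <- !is.na(anchors)
  onsets <- onsets[keep]; anchors <- anchors[keep]
  if (length(onsets) < 2) stop("need >= 2 instances with motif anchors")
  rel <- onsets - anchors
  stereo <- anchors + round(mean(rel))
  zl <- zs <- numeric(0)
  for (ch in channels) {
    for (bi in seq_len(nrow(bands))) {
      flt <- butter_bandpass_sos(4, bands$low[bi], bands$high[bi], rec$fs)
      ph <- Arg(analytic_signal(sosfiltfilt(flt, rec$voltage[ch, ]),
                                rec$fs))
      il <- itpc(ph[pmax(1, round(onsets) + 1L)])
      is_ <- itpc(ph[pmax(1, round(stereo) + 1L)])
      zl <- c(zl, il$Z); zs <- c(zs, is_$Z)
    }
  }
  diffs <- zl - zs
  p <- if (all(diffs == 0)) NA_real_ else
    stats::wilcox.test(diffs, alternative = "greater")$p.value
  list(difference = diffs, z_labeled = zl, z_stereotyped = zs, p = p,
       stereotyped_offset = round(mean(rel)))
}

#' Onset phase histogram for one band
#'
#' Samples the instantaneous phase at each labeled onset and summarises
#' the circular distribution: bin counts for a polar histogram, the mean
#' direction, resultant length and Rayleigh test.
#'
#' When several channels are pooled their polarity is first aligned to
#' the first channel by the sign of the narrowband trace correlation
#' (laminar probes commonly straddle a polarity inversion); phases of
#' inverted channels are rotated by pi before pooling.
#'
#' Two phase estimators are available.  `"wavelet"` (default) reads the
#' phase from a complex Morlet kernel at the band's geometric centre:
#' its compact (~35 ms SD) temporal support keeps activity tens of
#' milliseconds away from the onset out of the estimate, which matters
#' during rapid song sequences.  `"filter"` uses the zero-phase
#' band-pass + Hilbert phase at the onset sample; narrow IIR filters
#' smear neighbouring structure over ~1/bandwidth into the sample of
#' interest, so this estimator is kept for comparison.
#'
#' @param rec an `lfp_recording`.
#' @param onsets labeled onset samples (`n >= 10`).
#' @param band `c(low, high)` Hz.
#' @param channel channel index, or a vector of channels to pool.
#' @param n_bins histogram bins over `(-pi, pi]` (default 16).
#' @param method `"wavelet"` (default) or `"filter"`.
#' @param wavelet_sigma_ms temporal SD of the Morlet kernel (default
#'   35).
#' @return list: `phases`, `counts`, `breaks`, `mean_direction`, `r`,
#'   `Z`, `p`, `n` (`n` counts trials, not trials x channels: pooled
#'   channels are averaged within trial first).
#' @export
onset_phase_histogram <- function(rec, onsets, band, channel = 1,
                                  n_bins = 16,
                                  method = c("wavelet", "filter"),
                                  wavelet_sigma_ms = 35) {
  method <- match.arg(method)
  if (length(onsets) < 10) stop("need at least 10 onsets")
  ii <- round(onsets) + 1L              # 0-based sample -> R index
  fs <- rec$fs
  if (method == "wavelet") {
    fc <- sqrt(band[1] * band[2])
    sg <- wavelet_sigma_ms / 1000
    half <- round(3 * sg * fs)
    tt <- (-half:half) / fs
    kern <- exp(-tt^2 / (2 * sg^2)) * exp(-2i * pi * fc * tt)
    phase_of <- function(x) {
      vapply(ii, function(i0) {
        idx <- (i0 - half):(i0 + half)
        ok <- idx >= 1 & idx <= length(x)
        Arg(sum(x[idx[ok]] * kern[ok]))
      }, numeric(1))
    }
  } else {
    flt <- butter_bandpass_sos(4, band[1], band[2], fs)
    phase_of <- function(x) Arg(analytic_signal(x, fs))[ii]
  }
  flt_pol <- butter_bandpass_sos(4, band[1], band[2], fs)
  ref_trace <- NULL
  zsum <- 0
  for (ch in channel) {
    tr <- sosfiltfilt(flt_pol, rec$voltage[ch, ])
    if (is.null(ref_trace)) ref_trace <- tr
    pol <- sign(stats::cor(tr, ref_trace))
    ph_ch <- if (method == "wavelet") phase_of(rec$voltage[ch, ])
             else phase_of(tr)
    if (pol < 0) ph_ch <- wrap_angle(ph_ch + pi)
    zsum <- zsum + exp(1i * ph_ch)
  }
  ph <- Arg(zsum)                       # per-trial phase, channel-averaged
  res <- itpc(ph)
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  counts <- as.integer(table(cut(ph, breaks, include.lowest = TRUE)))
  list(phases = ph, counts = counts, breaks = breaks,
       mean_direction = as.numeric(res$mean_angle), r = as.numeric(res$r),
       Z = as.numeric(res$Z), p = as.numeric(res$p), n = length(ph))
}
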