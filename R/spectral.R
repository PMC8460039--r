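# Power-domain characterisation: VAP-normalised spectrograms, cross-trial
# z-scores, band-power traces and vocal-vs-silent power tests.

#' VAP-normalised spectrogram trials
#'
#' Computes the filterbank analytic amplitude per band, normalises each
#' band by its mean over the vocally active period, and cuts event-aligned
#' trial windows.
#'
#' @param rec an `lfp_recording`.
#' @param vap numeric `c(start, end)` sample interval (0-based, half
#'   open) used for normalisation; events and windows must lie inside.
#' @param events alignment sample indices (one trial per event).
#' @param window `c(before, after)` in seconds around each alignment
#'   point.
#' @param channel channel index to analyse.
#' @param n_bands,f_range filterbank geometry (see [filterbank()]).
#' @return object of class `spectrogram_trials`: array `s[band, time,
#'   trial]` of amplitudes expressed as a fraction of the band's VAP
#'   mean, the band table and time axis.
#' @export
normalized_spectrogram <- function(rec, vap, events,
                                   window = c(0.5, 0.5), channel = 1,
                                   n_bands = 100, f_range = c(2, 200)) {
  stopifnot(vap[1] >= 0, vap[2] <= ncol(rec$voltage))
  bands <- filterbank_bands(n_bands, f_range)
  vap_idx <- (vap[1] + 1L):vap[2]
  nb <- nrow(bands)
  nbef <- round(window[1] * rec$fs); naft <- round(window[2] * rec$fs)
  tlen <- nbef + naft + 1L
  s <- array(NA_real_, dim = c(nb, tlen, length(events)))
  x <- rec$voltage[channel, ]
  for (bi in seq_len(nb)) {
    flt <- butter_bandpass_sos(4, bands$low[bi], bands$high[bi], rec$fs)
    amp <- Mod(analytic_signal(sosfiltfilt(flt, x), rec$fs))
    mu <- mean(amp[vap_idx])
    if (mu <= 0 || !is.finite(mu)) stop("degenerate band: ", bi)
    amp <- amp / mu
    for (k in seq_along(events)) {
      i0 <- events[k] - nbef
      idx <- (i0 + 1L):(i0 + tlen)
      if (idx[1] < 1L || idx[tlen] > length(amp))
        stop("trial window outside recording at event ", k)
      s[bi, , k] <- amp[idx]
    }
  }
  structure(list(s = s, bands = bands, fs = rec$fs,
                 time = (seq_len(tlen) - nbef - 1L) / rec$fs),
            class = "spectrogram_trials")
}

#' Cross-trial z-scored rating of averaged spectrograms
#'
#' Centers every trial spectrogram per frequency by the grand mean over
#' time and trials, then divides the across-trial mean by the
#' across-trial standard deviation at each (frequency, time) point.
#' Values of about +/-2 bound an approximate 95% interval: large `|S|`
#' marks time-frequency structure that is consistent relative to its
#' trial-to-trial scatter.  Points with zero cross-trial variance are set
#' to 0 and flagged.
#'
#' @param trials a `spectrogram_trials` (or plain array `s[f, t, n]`).
#' @return list: matrix `S[f, t]`, logical `flagged[f, t]` marking
#'   zero-variance points.
#' @export
cross_trial_zscore <- function(trials) {
  s <- if (inherits(trials, "spectrogram_trials")) trials$s else trials
  stopifnot(length(dim(s)) == 3, dim(s)[3] >= 2)
  grand <- apply(s, 1, mean)                       # per-frequency mean
  shat <- sweep(s, 1, grand)
  m <- apply(shat, c(1, 2), mean)
  sdv <- apply(shat, c(1, 2), stats::sd)
  flagged <- sdv == 0 | !is.finite(sdv)
  S <- m / sdv
  S[flagged] <- 0
  list(S = S, flagged = flagged)
}

#' Z-scored band-power trace
#'
#' Analytic amplitude of one broadband range (default 50-200 Hz),
#' smoothed with a centered rolling mean (default 50 ms) and z-scored
#' over the VAP.
#'
#' @param rec an `lfp_recording`.
#' @param band `c(low, high)` Hz.
#' @param smooth rolling-mean window in seconds.
#' @param channel channel index.
#' @param vap `c(start, end)` samples; defaults to the full extent.
#' @return numeric trace, one value per sample of the VAP.
#' @export
band_power_trace <- function(rec, band = c(50, 200), smooth = 0.05,
                             channel = 1, vap = NULL) {
  if (band[2] >= rec$fs / 2) stop("band above Nyquist")
  if (is.null(vap)) vap <- c(0, ncol(rec$voltage))
  flt <- butter_bandpass_sos(4, band[1], band[2], rec$fs)
  amp <- Mod(analytic_signal(sosfiltfilt(flt, rec$voltage[channel, ]),
                             rec$fs))
  amp <- rolling_mean(amp, round(smooth * rec$fs))
  tr <- amp[(vap[1] + 1L):vap[2]]
  sdv <- stats::sd(tr)
  if (sdv == 0) {
    attr(tr, "flagged_constant") <- TRUE
    return(tr * 0)
  }
  (tr - mean(tr)) / sdv
}

#' Vocal-vs-silent power tests per band and channel
#'
#' One-sided two-sample z-test comparing the distribution of power
#' values during vocal intervals against silent intervals, per
#' (band, channel), with Benjamini-Hochberg correction across the whole
#' band x channel family.
#'
#' @param power_vocal,power_silent lists (indexed `[[channel]][[band]]`)
#'   or matrices (`channel x band` of list-columns) of numeric samples;
#'   simplest form: two arrays `channel x band x sample`.  Here: two
#'   lists of equal shape where element `[[c]][[b]]` is a numeric vector.
#' @param alternative `"greater"` tests vocal > silent (S6-style),
#'   `"less"` tests vocal < silent (S7-style).
#' @param alpha,q significance levels for p and BH q (default 0.05).
#' @return list: data.frame `table` (channel, band, z, p, q, significant)
#'   and `percent_significant` (over non-degenerate tests).
#' @export
power_state_tests <- function(power_vocal, power_silent,
                              alternative = c("greater", "less"),
                              alpha = 0.05, q = 0.05) {
  alternative <- match.arg(alternative)
  nc <- length(power_vocal)
  nb <- length(power_vocal[[1]])
  rows <- list()
  for (c in seq_len(nc)) for (b in seq_len(nb)) {
    xv <- power_vocal[[c]][[b]]; xs <- power_silent[[c]][[b]]
    if (length(xv) < 2 || length(xs) < 2) {
      z <- NA_real_; p <- NA_real_
    } else {
      se <- sqrt(stats::var(xv) / length(xv) + stats::var(xs) / length(xs))
      if (se == 0) { z <- NA_real_; p <- NA_real_ } else {
        z <- (mean(xv) - mean(xs)) / se
        p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
             else stats::pnorm(z)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(channel = c, band = b,
                                            z = z, p = p)
  }
  tab <- do.call(rbind, rows)
  tab$q <- NA_real_
  ok <- !is.na(tab$p)
  tab$q[ok] <- stats::p.adjust(tab$p[ok], method = "BH")
  tab$significant <- ok & tab$p < alpha & tab$q < q
  list(table = tab,
       percent_significant = 100 * mean(tab$significant[ok]))
}

#' Welch's t-test contrast of high-gamma power around bout end
#'
#' One-sided Welch's t-test per channel comparing summary power samples
#' between two conditions (e.g. the 100 ms before vs after bout
#' termination), BH-corrected across channels.
#'
#' @param before,after lists indexed by channel of numeric power samples.
#' @param alternative direction of the alternative for `before` vs
#'   `after` (default `"greater"`: power drops after).
#' @return data.frame channel, t, p, q, significant.
#' @export
postbout_power_tests <- function(before, after, alternative = "greater") {
  rows <- lapply(seq_along(before), function(c) {
    ht <- stats::t.test(before[[c]], after[[c]], alternative = alternative)
    data.frame(channel = c, t = unname(ht$statistic), p = ht$p.value)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$p < 0.05 & tab$q < 0.05
  tab
}
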