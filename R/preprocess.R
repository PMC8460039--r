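# Signal conditioning: FIR low-pass + decimation, common average
# referencing, the log-spaced Hilbert filterbank and phase/power signals.

#' Low-pass filter and decimate a raw recording
#'
#' Low-passes with a Hamming-window FIR filter at `cutoff` and
#' downsamples to `fs_out`.  The FIR group delay (`(ntaps-1)/2` samples)
#' is compensated by shifting the filter output, so a passband impulse at
#' input sample `k` peaks at output sample `round(k * fs_out / fs_in)`.
#'
#' @param rec an `lfp_recording` (e.g. at the native 30 kHz).
#' @param cutoff low-pass cutoff in Hz (default 400).
#' @param fs_out output rate in Hz (default 1000); `fs_in / fs_out` must
#'   be an integer.
#' @param ntaps FIR length (default `16 * decimation factor + 1`, e.g.
#'   481 taps at 30 kHz -> 1 kHz: passband flat to 0.2% and over 35 dB
#'   down 80 Hz above the cutoff).
#' @return decimated `lfp_recording` at `fs_out`.
#' @export
lowpass_decimate <- function(rec, cutoff = 400, fs_out = 1000,
                             ntaps = NULL) {
  stopifnot(inherits(rec, "lfp_recording"), rec$fs >= 2 * cutoff)
  q <- rec$fs / fs_out
  if (abs(q - round(q)) > 1e-9)
    stop("fs_out is not an integer divisor of the input rate; ",
         "resample with a polyphase method first")
  q <- round(q)
  if (is.null(ntaps)) ntaps <- 16L * q + 1L
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1L  # odd length: integer delay
  h <- signal::fir1(ntaps - 1L, cutoff / (rec$fs / 2), type = "low")
  delay <- (ntaps - 1L) / 2L
  n <- ncol(rec$voltage)
  out <- matrix(0, nrow = nrow(rec$voltage), ncol = length(seq(1, n, by = q)))
  for (c in seq_len(nrow(rec$voltage))) {
    # zero-pad both ends so the centered convolution is defined
    # everywhere; sides = 2 makes the output delay-free directly
    x <- c(numeric(delay), rec$voltage[c, ], numeric(delay))
    y <- stats::filter(x, h, method = "convolution", sides = 2)
    y <- as.numeric(y)[(delay + 1L):(delay + n)]
    out[c, ] <- y[seq(1, n, by = q)]
  }
  recording(out, fs_out, rec$channel_ids, rec$good_mask)
}

#' Common average reference
#'
#' Subtracts, per sample, the mean across good channels from each good
#' channel.  Bad channels pass through untouched.
#'
#' @param rec an `lfp_recording` with at least 2 good channels.
#' @return referenced `lfp_recording`.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  g <- rec$good_mask
  if (sum(g) < 2) stop("common average reference needs >= 2 good channels")
  avg <- colMeans(rec$voltage[g, , drop = FALSE])
  v <- rec$voltage
  v[g, ] <- sweep(v[g, , drop = FALSE], 2, avg)
  recording(v, rec$fs, rec$channel_ids, rec$good_mask)
}

#' Band-edge table for a log-spaced filterbank
#'
#' Band centers are geometrically spaced over `f_range`; each band's
#' half-power width equals the log step, so adjacent bands overlap at
#' half power.
#'
#' @param n_bands number of bands.
#' @param f_range `c(low, high)` in Hz.
#' @return data.frame `low`, `center`, `high` (Hz).
#' @export
filterbank_bands <- function(n_bands = 100, f_range = c(2, 200)) {
  stopifnot(n_bands >= 1, f_range[1] > 0, f_range[2] > f_range[1])
  centers <- geom_centers(f_range[1], f_range[2], n_bands)
  rho <- if (n_bands > 1) centers[2] / centers[1] else 2^(1 / 8)
  data.frame(low = centers / sqrt(rho), center = centers,
             high = centers * sqrt(rho))
}

#' Canonical analysis bands
#'
#' The five narrowband ranges carried through the phase-locking,
#' classification and onset analyses, plus two broadband summary
#' presets: `"broadband"` (50-200 Hz) and `"highgamma"` (80-200 Hz).
#' @return data.frame `name`, `low`, `high`.
#' @export
canonical_bands <- function() {
  data.frame(name = c("4-8", "8-12", "25-35", "35-50", "50-70",
                      "broadband", "highgamma"),
             low = c(4, 8, 25, 35, 50, 50, 80),
             high = c(8, 12, 35, 50, 70, 200, 200))
}

#' Hilbert filterbank decomposition
#'
#' Band-passes each (good) channel in `n_bands` partially overlapping
#' narrow bands that are equal width in log space, then Hilbert-transforms
#' each narrowband series to the analytic signal.  Filters are 4th-order
#' Butterworth band-passes run as second-order sections: forward-backward
#' (zero phase) by default, forward-only (causal, positive delay only)
#' when `causal = TRUE`.
#'
#' @param rec an `lfp_recording`.
#' @param n_bands number of bands (default 100).
#' @param f_range frequency range in Hz (default `c(2, 200)`).
#' @param bands optional explicit band table (`low`, `high` in Hz;
#'   overrides `n_bands`/`f_range`), e.g. a subset of
#'   [canonical_bands()].
#' @param causal logical; forward-only filtering for decoding features.
#' @param channels channel indices to decompose (default good channels).
#' @param order Butterworth prototype order (default 4).
#' @return object of class `band_decomposition`: complex array
#'   `analytic[channel, band, sample]` plus the band table and flags.
#' @export
filterbank <- function(rec, n_bands = 100, f_range = c(2, 200),
                       bands = NULL, causal = FALSE,
                       channels = which(rec$good_mask), order = 4) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (is.null(bands)) {
    if (n_bands < 1) stop("n_bands must be >= 1")
    if (f_range[1] <= 0 || f_range[2] >= rec$fs / 2)
      stop("f_range must lie within (0, fs/2)")
    bands <- filterbank_bands(n_bands, f_range)
  }
  if (any(bands$high >= rec$fs / 2)) stop("band above Nyquist")
  nb <- nrow(bands)
  n <- ncol(rec$voltage)
  arr <- array(complex(1), dim = c(length(channels), nb, n))
  for (bi in seq_len(nb)) {
    flt <- butter_bandpass_sos(order, bands$low[bi], bands$high[bi], rec$fs)
    for (ci in seq_along(channels)) {
      x <- rec$voltage[channels[ci], ]
      y <- if (causal) sosfilt(flt, x) else sosfiltfilt(flt, x)
      arr[ci, bi, ] <- analytic_signal(y, rec$fs)
    }
  }
  structure(list(analytic = arr, bands = bands, fs = rec$fs,
                 channels = channels,
                 channel_ids = rec$channel_ids[channels],
                 causal = causal),
            class = "band_decomposition")
}

#' @export
print.band_decomposition <- function(x, ...) {
  cat(sprintf("<band_decomposition> %d ch x %d bands x %d samples (%s)\n",
              dim(x$analytic)[1], dim(x$analytic)[2], dim(x$analytic)[3],
              if (x$causal) "causal" else "zero-phase"))
  invisible(x)
}

#' Phase and power signals of a band decomposition
#'
#' Power is the analytic amplitude `|z|` (all phase information
#' removed); phase is `sin(Arg(z))`, a bounded waveform in `[-1, 1]`
#' carrying no power information.
#'
#' @param bd a `band_decomposition`.
#' @return list with arrays `phase` and `power`, same dimensions as
#'   `bd$analytic`.
#' @export
phase_power <- function(bd) {
  stopifnot(inherits(bd, "band_decomposition"))
  list(phase = sin(Arg(bd$analytic)), power = Mod(bd$analytic))
}

#' Default per-band feature windows for onset prediction
#'
#' Bin width and pre-onset offset (ms) per canonical band, matched to
#' each band's causal group delay so the feature window covers the
#' anticipatory activity after forward-only filtering (narrow low bands
#' delay the signal by over 200 ms; 50-70 Hz by about 44 ms).  These
#' play the role of the per-frequency optimum a full
#' [hyperparameter_search()] would return.
#'
#' @return data.frame `name`, `low`, `high`, `bin_ms`, `offset_ms`.
#' @export
onset_windows <- function() {
  b <- canonical_bands()[1:5, ]
  b$bin_ms <- c(150, 150, 50, 75, 100)
  b$offset_ms <- c(5, 5, 5, 5, 5)
  b
}
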