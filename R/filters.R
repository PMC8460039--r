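# Butterworth band-pass as second-order sections.
#
# signal::butter() returns the filter as full numerator/denominator
# polynomials; at the narrow fractional bandwidths of the 100-band
# filterbank those polynomials are ill-conditioned and the recursion
# diverges.  We therefore design in zero-pole-gain form (analog prototype
# -> LP-to-BP transform -> bilinear transform) and run the filter as a
# cascade of biquads, which is stable at any bandwidth of interest.

#' Design a Butterworth band-pass filter as second-order sections
#'
#' @param order prototype low-pass order `n`; the band-pass has `2n` poles.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @return object of class `sos_filter`: a list of biquads, each with
#'   numerator `b` and denominator `a` (length-3, `a[1] == 1`), plus the
#'   design parameters.
#' @keywords internal
butter_bandpass_sos <- function(order, low, high, fs) {
  stopifnot(order >= 1, low > 0, high > low, high < fs / 2)
  # analog Butterworth prototype poles (left half-plane, unit cutoff)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # pre-warp band edges for the bilinear transform
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # LP -> BP: each prototype pole maps to a conjugate-free pair
  # s^2 - (p*bw) s + w0^2 = 0
  pb <- p_lp * bw / 2
  disc <- sqrt(pb^2 - w0^2 + 0i)
  poles <- c(pb + disc, pb - disc)          # 2*order analog poles
  # zeros: order at s = 0, order at infinity
  # bilinear transform z = (2fs + s)/(2fs - s)
  zd <- (2 * fs + poles) / (2 * fs - poles)
  # digital zeros: order at z = 1 (from s = 0), order at z = -1 (from inf)
  sos <- vector("list", order)
  # sort poles into conjugate pairs by imaginary part magnitude
  idx <- order(Mod(zd), decreasing = TRUE)
  zd <- zd[idx]
  # pair each pole with its conjugate partner
  used <- rep(FALSE, length(zd))
  pairs <- list()
  for (i in seq_along(zd)) {
    if (used[i]) next
    j <- which(!used & seq_along(zd) != i &
                 abs(zd - Conj(zd[i])) < 1e-8 * (1 + Mod(zd[i])))
    j <- if (length(j)) j[1] else which(!used & seq_along(zd) != i)[1]
    used[c(i, j)] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(zd[i], zd[j])
  }
  for (s in seq_len(order)) {
    pp <- pairs[[s]]
    a <- c(1, -Re(pp[1] + pp[2]), Re(pp[1] * pp[2]))
    b <- c(1, 0, -1)                        # zeros at +1 and -1
    sos[[s]] <- list(b = b, a = a)
  }
  flt <- structure(list(sos = sos, order = order, low = low, high = high,
                        fs = fs),
                   class = "sos_filter")
  # normalise to unit gain at the (geometric) centre frequency
  g <- Mod(sos_response(flt, sqrt(low * high)))
  flt$sos[[1]]$b <- flt$sos[[1]]$b / g
  flt
}

#' Frequency response of an SOS filter
#' @param flt an `sos_filter`.
#' @param f frequencies in Hz.
#' @return complex response at `f`.
#' @keywords internal
sos_response <- function(flt, f) {
  z <- exp(-2i * pi * f / flt$fs)
  h <- rep(1 + 0i, length(f))
  for (s in flt$sos) {
    h <- h * (s$b[1] + s$b[2] * z + s$b[3] * z^2) /
      (s$a[1] + s$a[2] * z + s$a[3] * z^2)
  }
  h
}

# One biquad, direct form: MA pass then AR recursion.
biquad <- function(b, a, x) {
  n <- length(x)
  v <- b[1] * x
  if (n > 1) v[2:n] <- v[2:n] + b[2] * x[1:(n - 1)]
  if (n > 2) v[3:n] <- v[3:n] + b[3] * x[1:(n - 2)]
  as.numeric(stats::filter(v, filter = -a[2:3], method = "recursive"))
}

#' Causal SOS filtering
#'
#' Forward-only application: output at sample `t` depends only on input
#' samples `<= t`.
#' @param flt an `sos_filter`.
#' @param x numeric vector.
#' @keywords internal
sosfilt <- function(flt, x) {
  for (s in flt$sos) x <- biquad(s$b, s$a, x)
  x
}

#' Zero-phase SOS filtering (forward-backward)
#'
#' Forward-backward application with odd reflection padding, the
#' `filtfilt` idiom; the effective magnitude response is `|H|^2` and the
#' net phase is zero.
#' @param flt an `sos_filter`.
#' @param x numeric vector.
#' @param pad padding length in samples (default 1 s worth, capped at
#'   `length(x) - 1`).
#' @keywords internal
sosfiltfilt <- function(flt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- round(flt$fs)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- sosfilt(flt, xp)
  y <- rev(sosfilt(flt, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Analytic signal via the FFT Hilbert transform
#'
#' @param x real vector.
#' @param fs sampling rate (Hz); used to size the reflection padding.
#' @param pad_s reflection padding in seconds trimmed after transform
#'   (default 1).
#' @return complex vector, `Re` = input, `Mod` = analytic amplitude,
#'   `Arg` = instantaneous phase.
#' @keywords internal
analytic_signal <- function(x, fs, pad_s = 1) {
  n0 <- length(x)
  pad <- min(round(pad_s * fs), n0 - 1L)
  if (pad > 0) {
    xp <- c(2 * x[1] - x[(pad + 1):2], x,
            2 * x[n0] - x[(n0 - 1):(n0 - pad)])
  } else xp <- x
  # extend to a 2-3-5-smooth length: fft is O(n log n) only for smooth n
  n_s <- stats::nextn(length(xp), c(2, 3, 5))
  if (n_s > length(xp)) xp <- c(xp, rep(xp[length(xp)], n_s - length(xp)))
  n <- length(xp)
  X <- stats::fft(xp)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  z[(pad + 1):(pad + n0)]
}
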