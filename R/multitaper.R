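# Multitaper power spectral density with Slepian (DPSS) tapers.

# DPSS tapers via the symmetric tridiagonal eigenproblem
# (Slepian 1978; Percival & Walden 1993 ch. 8).  Exact to machine
# precision and requires only base eigen().
dpss_tapers <- function(n, nw, k) {
  diag_main <- ((n - 1 - 2 * (0:(n - 1))) / 2)^2 * cos(2 * pi * nw / n)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  # normalise and fix sign convention (positive mean / positive first lag)
  for (j in seq_len(k)) {
    tj <- tap[, j]
    tj <- tj / sqrt(sum(tj^2))
    if (j %% 2 == 1) { if (sum(tj) < 0) tj <- -tj }
    else if (sum((n:1) * tj) < 0) tj <- -tj
    tap[, j] <- tj
  }
  tap
}

# cache: tapers are reused across trials of equal length
.taper_cache <- new.env(parent = emptyenv())

get_dpss <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (is.null(.taper_cache[[key]]))
    .taper_cache[[key]] <- dpss_tapers(n, nw, k)
  .taper_cache[[key]]
}

#' Multitaper PSD of a single window
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param nw time-bandwidth product (default 7.5, giving 14
#'   well-concentrated tapers for a 1 s window).
#' @param k number of tapers (default `2 * nw - 1`).
#' @param f_range frequency range retained (default `c(0, 200)` Hz).
#' @return list `freq`, `psd` (density, power per Hz).
#' @export
multitaper_psd <- function(x, fs, nw = 7.5, k = round(2 * nw - 1),
                           f_range = c(0, 200)) {
  n <- length(x)
  tap <- get_dpss(n, nw, k)
  x <- x - mean(x)
  spec <- matrix(0, nrow = n, ncol = k)
  for (j in seq_len(k)) spec[, j] <- Mod(stats::fft(x * tap[, j]))^2
  psd <- rowMeans(spec) / fs
  freq <- (0:(n - 1)) * fs / n
  keep <- freq >= f_range[1] & freq <= min(f_range[2], fs / 2)
  # one-sided scaling (double all bins except DC/Nyquist)
  sc <- ifelse(freq > 0 & abs(freq - fs / 2) > 1e-9, 2, 1)
  list(freq = freq[keep], psd = (psd * sc)[keep])
}

#' Multitaper PSD trial ensemble around events
#'
#' One PSD per 1 s (by default) window centered on each event time, with
#' a condition label per trial.  Windows that exceed the recording are
#' dropped with a warning.
#'
#' @param rec an `lfp_recording`.
#' @param events named list of numeric vectors of alignment sample
#'   indices, one element per condition (e.g. `list(active = ...,
#'   inactive = ...)`).
#' @param window trial length in seconds (default 1).
#' @param channel channel index.
#' @param nw,k multitaper parameters (see [multitaper_psd()]).
#' @param f_range frequency range (default `c(0, 200)`).
#' @param balance logical: downselect conditions to equal counts
#'   (deterministic: first `n` of each).
#' @return object of class `psd_ensemble`: matrix `P[freq, trial]`,
#'   `freq`, `condition` (factor per trial).
#' @export
multitaper_trials <- function(rec, events, window = 1, channel = 1,
                              nw = 7.5, k = 14, f_range = c(0, 200),
                              balance = TRUE) {
  n <- round(window * rec$fs)
  half <- n %/% 2
  x <- rec$voltage[channel, ]
  Ps <- list(); cond <- character(0)
  for (cn in names(events)) {
    for (t0 in events[[cn]]) {
      i0 <- round(t0) - half
      if (i0 < 0 || i0 + n > length(x)) {
        warning("trial window outside recording; dropped")
        next
      }
      p <- multitaper_psd(x[(i0 + 1L):(i0 + n)], rec$fs, nw, k, f_range)
      Ps[[length(Ps) + 1L]] <- p$psd
      cond <- c(cond, cn)
      freq <- p$freq
    }
  }
  if (length(Ps) < 2) stop("fewer than 2 usable trials")
  P <- do.call(cbind, Ps)
  if (balance && length(unique(cond)) > 1) {
    nmin <- min(table(cond))
    keep <- unlist(lapply(unique(cond),
                          function(cn) which(cond == cn)[seq_len(nmin)]))
    keep <- sort(keep)
    P <- P[, keep, drop = FALSE]
    cond <- cond[keep]
  }
  structure(list(P = P, freq = freq, condition = factor(cond)),
            class = "psd_ensemble")
}
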