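# Generative LFP model: 1/f background, event-locked narrowband
# transients with class-specific preferred phases, class waveform
# templates, and broadband high-gamma elevation during vocalisation.

#' Construct a generative LFP model
#'
#' The synthetic LFP is the sum of (i) `1/f^alpha` Gaussian background,
#' partially shared across channels, whose `> 50` Hz part is multiplied
#' by `highgamma_gain` during vocal intervals; (ii) per-band oscillatory
#' transients added around every vocal-event onset whose phase at the
#' onset sample is drawn von Mises around the event class's preferred
#' phase with concentration `kappa` (`Inf` = exact reset); and (iii) a
#' small fixed broadband waveform per class (added in a window around
#' the onset) that makes class identity recoverable from amplitude as
#' well as phase.
#' Channels receive alternating-sign gains, emulating laminar polarity
#' inversion across the probe, so common-average referencing does not
#' cancel the event-locked signal.
#'
#' @param classes vocal class labels the model assigns preferred phases
#'   and templates to.
#' @param bands data.frame with columns `low`, `high` (Hz), `amplitude`
#'   (in units of the background SD) and `kappa` (von Mises
#'   concentration, `>= 0`, may be `Inf`).
#' @param preferred_phase optional classes x bands matrix of preferred
#'   onset phases (radians).  Default spreads classes evenly around the
#'   circle with a band-dependent rotation.
#' @param highgamma_gain multiplicative gain applied to the `> 50` Hz
#'   background during vocal intervals (default 2).
#' @param background_exponent `alpha` of the `1/f^alpha` background
#'   (default 1).
#' @param background_sd background standard deviation; 0 disables the
#'   background entirely.
#' @param channel_count number of channels (default 16).
#' @param shared_noise_fraction fraction of background variance shared
#'   across channels, in `[0, 1]`.
#' @param fs sampling rate (Hz, default 1000).
#' @param transient_center_ms centre of the transient envelope relative
#'   to the event onset (default -30: premotor bursts peak shortly
#'   before the vocal gesture, as expected of a premotor nucleus, which
#'   also leaves usable pre-onset energy after causal filtering).
#' @param transient_sigma_ms cap (ms) on the SD of the Gaussian
#'   transient envelope; each band uses roughly two carrier cycles
#'   (floored at 0.8 cycles), so gamma bursts are short sharp
#'   deflections while low-frequency bands are widened to
#'   `800 / f_center` ms so every burst spans a few cycles.  The Gaussian
#'   (Morlet-style) envelope keeps bursts compact in time and frequency
#'   at once: adjacent bands and adjacent syllables barely leak into one
#'   another.
#' @param template_snr amplitude of the class waveform template in units
#'   of the background SD (default 1.8: the anticipatory signature is
#'   the dominant event-locked feature, as premotor potentials are in
#'   HVC).
#' @param template_gain optional named numeric of per-class multipliers
#'   on `template_snr`; the default gives the intra-motif connector
#'   note (label "c", when present among `classes`) a doubled
#'   signature: producing an optional song element is preceded by
#'   distinctively strong preparatory activity.
#' @param template_lead_ms class-template window start before the onset
#'   (default 140).
#' @param template_dur_ms class-template window length (default 70; the
#'   window [-140, -70] ms is far enough from the onset sample that the
#'   zero-phase filters' smear cannot carry its fixed-phase content
#'   there, and at the default song tempo it stays clear of the
#'   preceding element's onset as well).
#' @param seed integer seed owning all of the model's randomness.
#' @return an object of class `lfp_model`.
#' @export
lfp_model <- function(classes,
                      bands = data.frame(
                        low = c(4, 8, 25, 35, 50),
                        high = c(8, 12, 35, 50, 70),
                        amplitude = c(0.55, 0.55, 0.65, 0.65, 0.5),
                        kappa = 24),
                      preferred_phase = NULL,
                      highgamma_gain = 2,
                      background_exponent = 1,
                      background_sd = 1,
                      channel_count = 16,
                      shared_noise_fraction = 0.2,
                      fs = 1000,
                      transient_center_ms = 0,
                      transient_sigma_ms = 55,
                      template_snr = 1.8,
                      template_gain = c("c" = 2),
                      template_lead_ms = 140,
                      template_dur_ms = 70,
                      seed = 1) {
  stopifnot(length(classes) >= 1, is.data.frame(bands),
            all(c("low", "high", "amplitude", "kappa") %in% names(bands)),
            shared_noise_fraction >= 0, shared_noise_fraction <= 1,
            all(bands$kappa >= 0), fs > 0, channel_count >= 1,
            transient_sigma_ms > 0)
  if (any(bands$low <= 0) || any(bands$high <= bands$low))
    stop("band edges must be strictly increasing and positive")
  if (any(bands$high >= fs / 2)) stop("band above Nyquist")
  nb <- nrow(bands)
  if (is.null(preferred_phase)) {
    preferred_phase <- outer(seq_along(classes) - 1L, seq_len(nb) - 1L,
                             function(i, b) wrap_angle(2 * pi * i / length(classes) +
                                                         b * pi / (2 * nb)))
    dimnames(preferred_phase) <- list(classes, NULL)
  }
  stopifnot(nrow(preferred_phase) == length(classes),
            ncol(preferred_phase) == nb)
  # fixed per-channel gains: alternating polarity (laminar inversion),
  # magnitudes deterministic in the seed
  set.seed(child_seed(seed, "channel-gains"))
  gains <- (1 + 0.5 * stats::runif(channel_count, -1, 1)) *
    rep_len(c(1, -1), channel_count)
  # fixed class templates: anticipatory broadband (4-150 Hz) waveforms
  # in a window that ends well before the onset.  They give the causal
  # decoders and the onset predictor a class-specific premotor cue in
  # every analysis band; because the window closes 70 ms before the
  # onset sample (and is taper-ended), they cannot bias the onset
  # phases of the locked bursts.
  set.seed(child_seed(seed, "class-templates"))
  nt <- round(template_dur_ms / 1000 * fs)
  tt <- seq_len(nt) / fs
  templates <- lapply(classes, function(cl) {
    # dense spectral content, stratified so every analysis band holds
    # several components: the waveform is noise-like with a sharp
    # autocorrelation in each band, and a matched filter can localise
    # it to a few ms regardless of which band it looks through
    strata <- rbind(c(4, 8), c(8, 12), c(25, 35), c(35, 50), c(50, 70),
                    c(70, 110), c(110, 150))
    f <- as.numeric(apply(strata, 1, function(b)
      stats::runif(5, b[1], b[2])))
    ph <- stats::runif(length(f), 0, 2 * pi)
    a <- stats::runif(length(f), 0.3, 1)
    # the locked analysis bands carry half weight: enough for matched
    # filtering, low enough that filter smear of this fixed-phase
    # waveform cannot bias the measured onset phases
    a <- a * rep(c(0.5, 1), c(25, 10))
    w <- colSums(a * sin(outer(2 * pi * f, tt) + ph))
    w <- w / stats::sd(w)
    gn <- if (!is.null(template_gain) && cl %in% names(template_gain))
      template_gain[[cl]] else 1
    w * gn
  })
  names(templates) <- classes
  # class-specific slow amplitude modulation: a shallow Gaussian bump
  # whose centre/width differ per class, so class identity is
  # recoverable from power alone; shallow and slow so it cannot distort
  # the instantaneous phase at onset
  set.seed(child_seed(seed, "class-envelopes"))
  envelopes <- lapply(classes, function(cl) {
    list(center_s = stats::runif(1, -0.12, -0.04),
         width_s = stats::runif(1, 0.05, 0.1),
         depth = 0.5)
  })
  names(envelopes) <- classes
  structure(list(classes = classes, bands = bands,
                 preferred_phase = preferred_phase,
                 highgamma_gain = highgamma_gain,
                 background_exponent = background_exponent,
                 background_sd = background_sd,
                 channel_count = channel_count,
                 shared_noise_fraction = shared_noise_fraction,
                 fs = fs, transient_center_ms = transient_center_ms,
                 transient_sigma_ms = transient_sigma_ms,
                 template_snr = template_snr,
                 template_lead_ms = template_lead_ms,
                 template_dur_ms = template_dur_ms,
                 channel_gains = gains, class_templates = templates,
                 class_envelopes = envelopes,
                 seed = seed),
            class = "lfp_model")
}

#' @export
print.lfp_model <- function(x, ...) {
  cat(sprintf("<lfp_model> %d ch @ %g Hz, %d locked bands, alpha=%g, hg_gain=%g\n",
              x$channel_count, x$fs, nrow(x$bands),
              x$background_exponent, x$highgamma_gain))
  invisible(x)
}

# 1/f^alpha shaped Gaussian noise; returns list(low, high): the < split_hz
# and >= split_hz parts (linear split in the frequency domain).
shaped_background <- function(white, fs, alpha, split_hz = 50) {
  n0 <- length(white)
  n_s <- stats::nextn(n0, c(2, 3, 5))
  if (n_s > n0) white <- c(white, stats::rnorm(n_s - n0))
  n <- length(white)
  f <- c(0, seq_len(n - 1)) / n * fs
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  shape <- ifelse(f > 0, f^(-alpha / 2), 0)
  W <- stats::fft(white) * shape
  lowmask <- as.numeric(f < split_hz)
  low <- Re(stats::fft(W * lowmask, inverse = TRUE)) / n
  high <- Re(stats::fft(W * (1 - lowmask), inverse = TRUE)) / n
  list(low = low[seq_len(n0)], high = high[seq_len(n0)])
}

#' Synthesize a multichannel LFP recording from annotations
#'
#' @param ann an `annotation_set` (e.g. from [sample_behavior()]).
#' @param model an [lfp_model()].  Classes absent from the model's
#'   `classes` receive no transient or template (background only).
#' @return an `lfp_recording` of `model$channel_count` channels at
#'   `model$fs`, reproducible bitwise for fixed `(ann, model)`.
#' @export
synthesize_lfp <- function(ann, model) {
  stopifnot(inherits(ann, "annotation_set"), inherits(model, "lfp_model"))
  ev <- vocal_events(ann)
  if (!nrow(ev)) stop("annotations contain no vocal events")
  if (any(model$bands$high >= model$fs / 2)) stop("band above Nyquist")
  fs <- model$fs
  stopifnot(abs(fs - ann$fs) < 1e-9)
  n <- max(ev$offset) + 2 * fs
  C <- model$channel_count
  v <- matrix(0, nrow = C, ncol = n)
  # --- background -----------------------------------------------------
  if (model$background_sd > 0) {
    set.seed(child_seed(model$seed, "background"))
    voc_env <- numeric(n)
    for (i in seq_len(nrow(ev)))
      voc_env[(ev$onset[i] + 1L):min(n, ev$offset[i])] <- 1
    voc_env <- rolling_mean(voc_env, round(0.01 * fs))
    hg <- 1 + (model$highgamma_gain - 1) * voc_env
    zsh <- stats::rnorm(n)
    sh <- model$shared_noise_fraction
    for (c in seq_len(C)) {
      w <- sqrt(sh) * zsh + sqrt(1 - sh) * stats::rnorm(n)
      parts <- shaped_background(w, fs, model$background_exponent)
      x <- parts$low + parts$high * hg
      # normalise silent-period SD to background_sd
      v[c, ] <- x / stats::sd(parts$low + parts$high) * model$background_sd
    }
  }
  # --- event-locked transients and class templates --------------------
  set.seed(child_seed(model$seed, "phases"))
  centers <- sqrt(model$bands$low * model$bands$high)
  # per-band envelope SD: roughly two carrier cycles, floored at 0.8
  # cycles and capped at transient_sigma_ms -- gamma bursts are short,
  # sharp, evoked-potential-like deflections; low-frequency bursts span
  # several hundred ms
  sigmas <- pmax(800 / centers,
                 pmin(model$transient_sigma_ms, 2075 / centers)) / 1000
  gains <- model$channel_gains
  tpl_lead <- round(model$template_lead_ms / 1000 * fs)
  tpl_n <- round(model$template_dur_ms / 1000 * fs)
  tpl_env <- tukey_window(tpl_n, 1)
  known <- ev$label %in% model$classes
  for (i in which(known)) {
    cl <- ev$label[i]
    on_i <- ev$onset[i]
    cl_env <- model$class_envelopes[[cl]]
    for (b in seq_len(nrow(model$bands))) {
      phi <- rvonmises(1, model$preferred_phase[cl, b],
                       model$bands$kappa[b])
      ctr <- round(model$transient_center_ms / 1000 * fs)
      half <- round(4 * sigmas[b] * fs)
      idx <- (on_i + ctr - half + 1L):(on_i + ctr + half + 1L)
      ok <- idx >= 1L & idx <= n
      rel <- (idx - 1L - on_i) / fs          # time rel. to onset (s)
      env <- exp(-(rel - model$transient_center_ms / 1000)^2 /
                   (2 * sigmas[b]^2))
      mod <- 1 + cl_env$depth *
        exp(-(rel - cl_env$center_s)^2 / (2 * cl_env$width_s^2))
      wave <- model$bands$amplitude[b] * model$background_sd *
        env * mod * cos(2 * pi * centers[b] * rel + phi)
      v[, idx[ok]] <- v[, idx[ok]] + outer(gains, wave[ok])
    }
    # additive high-band class waveform in a fixed pre/peri-onset window
    t0 <- on_i - tpl_lead
    idx <- (t0 + 1L):(t0 + tpl_n)
    ok <- idx >= 1L & idx <= n
    wave <- model$template_snr * model$background_sd *
      (model$class_templates[[cl]] * tpl_env)
    v[, idx[ok]] <- v[, idx[ok]] + outer(gains, wave[ok])
  }
  recording(v, fs)
}

# Tukey (tapered cosine) window, flat in the middle.
tukey_window <- function(n, alpha = 0.3) {
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}
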