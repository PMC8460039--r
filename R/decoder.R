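# Template-Pearson feature extraction and LDA classification.
#
# Feature layout: one Pearson correlation per (class template x channel)
# for a given frequency band; feature modes select the underlying trace
# (raw band-passed voltage, phase-only sin(Arg z), or power-only |z|),
# always from causal filters so every feature precedes the event onset.

#' Causal feature signals for one band
#'
#' @param rec an `lfp_recording` (already common-average referenced for
#'   the decoding analyses).
#' @param band `c(low, high)` Hz.
#' @param mode `"raw"`, `"phase_only"` or `"power_only"`.
#' @param channels channel indices (default good channels).
#' @param causal forward-only filtering (default `TRUE`).
#' @return matrix `channels x samples`.
#' @export
feature_signals <- function(rec, band, mode = c("raw", "phase_only",
                                                "power_only"),
                            channels = which(rec$good_mask),
                            causal = TRUE) {
  mode <- match.arg(mode)
  flt <- butter_bandpass_sos(4, band[1], band[2], rec$fs)
  out <- matrix(0, length(channels), ncol(rec$voltage))
  for (i in seq_along(channels)) {
    y <- if (causal) sosfilt(flt, rec$voltage[channels[i], ])
         else sosfiltfilt(flt, rec$voltage[channels[i], ])
    out[i, ] <- switch(mode,
      raw = y,
      phase_only = sin(Arg(analytic_signal(y, rec$fs))),
      power_only = Mod(analytic_signal(y, rec$fs)))
  }
  out
}

# Feature window of an event: 0-based half-open [onset-offset-bin,
# onset-offset) -> R indices.  Returns NULL if it collides with the
# recording start.
event_window <- function(onset, bin_smp, offset_smp, n) {
  a <- round(onset) - offset_smp - bin_smp   # 0-based start
  if (a < 0 || a + bin_smp > n) return(NULL)
  (a + 1L):(a + bin_smp)
}

#' Build per-class band templates from training events
#'
#' The template of a class is the element-wise mean, across its training
#' instances, of the feature trace in the window `[onset - offset - bin,
#' onset - offset)`.  Windows that collide with the recording start are
#' dropped and counted in `n_dropped`.
#'
#' @param signals matrix `channels x samples` from [feature_signals()].
#' @param events named list: class -> training onset samples.
#' @param bin_ms,offset_ms window length and pre-onset offset in ms.
#' @param fs sampling rate (Hz).
#' @return object of class `template_bank`: `templates[[class]]` is a
#'   `channels x bin` matrix, plus the window parameters.
#' @export
build_templates <- function(signals, events, bin_ms, offset_ms, fs) {
  stopifnot(offset_ms > 0, bin_ms > 0)
  bin_smp <- round(bin_ms / 1000 * fs)
  off_smp <- round(offset_ms / 1000 * fs)
  n <- ncol(signals)
  n_dropped <- 0L
  templates <- lapply(events, function(onsets) {
    acc <- matrix(0, nrow(signals), bin_smp)
    m <- 0L
    for (t0 in onsets) {
      idx <- event_window(t0, bin_smp, off_smp, n)
      if (is.null(idx)) { n_dropped <<- n_dropped + 1L; next }
      acc <- acc + signals[, idx, drop = FALSE]
      m <- m + 1L
    }
    if (m == 0L) stop("no usable training instances for a class")
    acc / m
  })
  structure(list(templates = templates, bin_ms = bin_ms,
                 offset_ms = offset_ms, bin_smp = bin_smp,
                 offset_smp = off_smp, fs = fs, n_dropped = n_dropped),
            class = "template_bank")
}

#' Pearson correlation feature
#'
#' Standard Pearson r between a trace segment and a template of the same
#' length, bounded in `[-1, 1]`.  A zero-variance segment or template
#' yields 0 (an uninformative feature) rather than `NaN`.
#'
#' @param segment,template numeric vectors of equal length.
#' @export
pearson_feature <- function(segment, template) {
  if (length(segment) != length(template))
    stop("segment and template lengths differ")
  if (stats::sd(segment) == 0 || stats::sd(template) == 0) return(0)
  stats::cor(segment, template)
}

# Feature matrix: one row per event, one column per (class x channel).
extract_features <- function(signals, onsets, bank) {
  classes <- names(bank$templates)
  nc <- nrow(signals)
  X <- matrix(0, length(onsets), length(classes) * nc)
  for (e in seq_along(onsets)) {
    idx <- event_window(onsets[e], bank$bin_smp, bank$offset_smp,
                        ncol(signals))
    if (is.null(idx)) next                     # all-zero feature row
    col <- 1L
    for (cl in classes) for (c in seq_len(nc)) {
      X[e, col] <- pearson_feature(signals[c, idx],
                                   bank$templates[[cl]][c, ])
      col <- col + 1L
    }
  }
  X
}

# Fit LDA on training features, predict test; equal priors, drop
# zero-variance columns (they carry nothing and break MASS::lda).
lda_fit_predict <- function(Xtr, ytr, Xte) {
  keep <- apply(Xtr, 2, stats::sd) > 0
  if (!any(keep)) return(rep(levels(ytr)[1], nrow(Xte)))
  fit <- suppressWarnings(
    MASS::lda(Xtr[, keep, drop = FALSE], grouping = ytr,
              prior = rep(1 / nlevels(ytr), nlevels(ytr))))
  as.character(stats::predict(fit, Xte[, keep, drop = FALSE])$class)
}

#' Binomial chance level
#'
#' The smallest accuracy whose upper-tail probability under
#' `Binomial(N, 1/k)` is below `p`: the bar a classifier of `N` balanced
#' events over `k` classes must clear to beat chance.
#'
#' @param n_events total event count `N`.
#' @param n_classes class count `k`.
#' @param p tail probability (default 0.05).
#' @return accuracy in `[0, 1]`.
#' @export
binomial_chance <- function(n_events, n_classes, p = 0.05) {
  m <- stats::qbinom(1 - p, n_events, 1 / n_classes) + 1L
  m / n_events
}

#' LDA classification of balanced event classes
#'
#' 5-fold stratified cross-validation; templates are recomputed from the
#' training fold only, and the same seeded fold partition is reused for
#' paired comparisons across feature modes.
#'
#' @param signals matrix `channels x samples` (see [feature_signals()]);
#'   for `mode = "both"` pass `list(phase = ..., power = ...)`.
#' @param event_sets named list of [event_set()] objects (balanced).
#' @param bin_ms,offset_ms feature window parameters.
#' @param fs sampling rate (Hz).
#' @param folds number of CV folds (default 5).
#' @param seed seed for the fold partition.
#' @return object of class `classifier_report`: per-fold accuracies,
#'   mean/SD, confusion matrix, chance level, fold assignment.
#' @export
classify_events <- function(signals, event_sets, bin_ms = 100,
                            offset_ms = 10, fs = 1000, folds = 5,
                            seed = 1) {
  onsets <- unlist(lapply(event_sets, function(e) e$times), use.names = FALSE)
  labels <- factor(rep(names(event_sets),
                       vapply(event_sets, function(e) length(e$times),
                              integer(1))))
  if (min(table(labels)) < folds)
    stop("every class needs at least as many events as folds")
  fold <- stratified_folds(as.character(labels), folds, seed)
  sig_list <- if (is.matrix(signals)) list(signals) else signals
  pred <- character(length(onsets))
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- Xte <- NULL
    for (sg in sig_list) {
      ev_tr <- split(onsets[tr], labels[tr])
      bank <- build_templates(sg, ev_tr, bin_ms, offset_ms, fs)
      Xtr <- cbind(Xtr, extract_features(sg, onsets[tr], bank))
      Xte <- cbind(Xte, extract_features(sg, onsets[!tr], bank))
    }
    pred[!tr] <- lda_fit_predict(Xtr, droplevels(labels[tr]), Xte)
  }
  acc_fold <- vapply(seq_len(folds), function(f)
    mean(pred[fold == f] == labels[fold == f]), numeric(1))
  structure(list(accuracy = mean(pred == labels),
                 fold_accuracy = acc_fold,
                 sd = stats::sd(acc_fold),
                 confusion = table(truth = labels, predicted = pred),
                 chance = binomial_chance(length(onsets),
                                          nlevels(labels)),
                 n_events = length(onsets),
                 n_classes = nlevels(labels),
                 fold = fold),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> accuracy %.3f (fold SD %.3f), chance %.3f (N=%d, k=%d)\n",
              x$accuracy, x$sd, x$chance, x$n_events, x$n_classes))
  invisible(x)
}

#' Bin-width / offset hyperparameter search
#'
#' Cross-validated accuracy on a grid of feature-window parameters; all
#' windows precede the vocal onset by construction (`offset > 0`).
#' The argmax is reported with ties broken toward the smaller bin width,
#' then the smaller offset.
#'
#' @param signals,event_sets,fs,folds,seed as in [classify_events()].
#' @param bin_widths,offsets candidate values in ms.
#' @return list: `grid` (data.frame bin_ms, offset_ms, accuracy),
#'   `best` (row of `grid`).
#' @export
hyperparameter_search <- function(signals, event_sets, fs = 1000,
                                  bin_widths = c(20, 30, 50, 75, 100,
                                                 150, 200),
                                  offsets = c(5, 10, 20, 30, 50, 75, 100),
                                  folds = 5, seed = 1) {
  if (!length(bin_widths) || !length(offsets)) stop("empty grid")
  grid <- expand.grid(bin_ms = sort(bin_widths), offset_ms = sort(offsets))
  grid$accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    rep <- classify_events(signals, event_sets, grid$bin_ms[i],
                           grid$offset_ms[i], fs, folds, seed)
    grid$accuracy[i] <- rep$accuracy
  }
  ord <- order(-grid$accuracy, grid$bin_ms, grid$offset_ms)
  list(grid = grid, best = grid[ord[1], ])
}

#' Channel-adding bootstrap curve
#'
#' Repeatedly classifies with the features of the first `c` channels of
#' a random channel order, for `c = 1 ... C`; the order is drawn per
#' repetition and maintained across folds.  Reports mean and SD of
#' accuracy per channel count over repetitions.
#'
#' @param signals matrix `channels x samples` (or list for mode
#'   `"both"`).
#' @param event_sets named list of [event_set()]s.
#' @param n_reps repetitions (paper default 5000).
#' @param bin_ms,offset_ms,fs,folds,seed as in [classify_events()].
#' @return data.frame: n_channels, mean_accuracy, sd_accuracy.
#' @export
channel_adding <- function(signals, event_sets, n_reps = 5000,
                           bin_ms = 100, offset_ms = 10, fs = 1000,
                           folds = 5, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  sig_list <- if (is.matrix(signals)) list(signals) else signals
  C <- nrow(sig_list[[1]])
  if (C < 2) stop("channel adding needs >= 2 channels")
  set.seed(child_seed(seed, "channel-orders"))
  orders <- replicate(n_reps, sample.int(C), simplify = FALSE)
  acc <- matrix(NA_real_, n_reps, C)
  for (r in seq_len(n_reps)) {
    ord <- orders[[r]]
    for (cc in seq_len(C)) {
      sub <- lapply(sig_list, function(sg) sg[ord[seq_len(cc)], ,
                                              drop = FALSE])
      if (length(sub) == 1L) sub <- sub[[1]]
      rep_ <- classify_events(sub, event_sets, bin_ms, offset_ms, fs,
                              folds, seed)
      acc[r, cc] <- rep_$accuracy
    }
  }
  data.frame(n_channels = seq_len(C),
             mean_accuracy = colMeans(acc),
             sd_accuracy = apply(acc, 2, stats::sd))
}

#' Phase-only / power-only / both feature ablations
#'
#' Classifies the same events with the same fold partition under three
#' feature modes; `"both"` concatenates the phase and power features.
#'
#' @param rec an `lfp_recording`.
#' @param event_sets named list of [event_set()]s.
#' @param band `c(low, high)` Hz.
#' @param bin_ms,offset_ms,folds,seed as in [classify_events()].
#' @param channels channel indices.
#' @return named list of `classifier_report`s:
#'   `phase_only`, `power_only`, `both`.
#' @export
ablate <- function(rec, event_sets, band, bin_ms = 100, offset_ms = 10,
                   folds = 5, seed = 1,
                   channels = which(rec$good_mask)) {
  sp <- feature_signals(rec, band, "phase_only", channels)
  sw <- feature_signals(rec, band, "power_only", channels)
  list(phase_only = classify_events(sp, event_sets, bin_ms, offset_ms,
                                    rec$fs, folds, seed),
       power_only = classify_events(sw, event_sets, bin_ms, offset_ms,
                                    rec$fs, folds, seed),
       both = classify_events(list(phase = sp, power = sw), event_sets,
                              bin_ms, offset_ms, rec$fs, folds, seed))
}
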