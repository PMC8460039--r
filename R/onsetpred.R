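# Naive template-matching syllable-onset prediction.

# Sliding Pearson correlation of x against a fixed template, vectorised
# via running sums.  Output is indexed by putative onset sample t
# (0-based): value at t correlates the segment [t - offset - bin,
# t - offset) with the template.  Samples whose window collides with the
# signal start are NA.
sliding_pearson <- function(x, template, bin_smp, offset_smp) {
  n <- length(x)
  tc <- template - mean(template)
  st <- sqrt(sum(tc^2))
  if (st == 0) return(rep(0, n))
  # dot product of every window [a+1, a+bin] with tc, a = 0..n-bin
  num <- stats::filter(x, rev(tc), method = "convolution", sides = 1)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  b <- seq_len(n)                  # window end index (R, inclusive)
  a <- b - bin_smp                 # window start - 1
  valid <- a >= 0
  sx <- sx2 <- rep(NA_real_, n)
  sx[valid] <- cs[b[valid]] - ifelse(a[valid] == 0, 0, cs[a[valid]])
  sx2[valid] <- cs2[b[valid]] - ifelse(a[valid] == 0, 0, cs2[a[valid]])
  denom <- sqrt(pmax(sx2 - sx^2 / bin_smp, 0)) * st
  r_end <- (as.numeric(num)) / denom
  r_end[!is.finite(r_end)] <- 0
  r_end <- pmin(pmax(r_end, -1), 1)   # guard running-sum roundoff
  # window ending at R index b covers 0-based [b - bin, b); putative
  # onset t has window ending at 0-based t - offset, i.e. R index
  # t - offset.  So conf[t (0-based) + 1] = r_end[t - offset].
  shift <- offset_smp
  conf <- rep(NA_real_, n)
  src <- seq_len(n) - 1L - shift             # R index into r_end
  ok <- src >= bin_smp & src <= n
  conf[ok] <- r_end[src[ok]]
  conf
}

#' Naive prediction-confidence trace for one syllable class
#'
#' For every time point `t`, correlates the causal feature trace ending
#' `offset` ms before `t` (length = bin width) against the class
#' template, per channel; negative correlations are clipped to zero and
#' the result is averaged across channels.  With multiple bands
#' (`signals` and `banks` as parallel lists) the average additionally
#' runs over bands: the all-frequency predictor.
#'
#' @param signals matrix `channels x samples`, or list of such matrices
#'   (one per band).
#' @param banks a `template_bank` (or parallel list of banks) holding the
#'   class's template and window parameters.
#' @param class class label whose template is used.
#' @param combine `"mean"` (default) or `"max"` across channels/bands.
#' @param by_band also return each band's own channel-averaged trace
#'   (the per-frequency predictors) alongside the combined one.
#' @return numeric confidence trace in `[0, 1]`, indexed by putative
#'   onset sample (0-based sample `t` at position `t + 1`); `NA` where
#'   the window precedes the recording.  With `by_band = TRUE`, a list
#'   `all` (combined) and `band` (list of per-band traces).
#' @export
confidence_trace <- function(signals, banks, class, combine = c("mean",
                                                                "max"),
                             by_band = FALSE) {
  combine <- match.arg(combine)
  sig_list <- if (is.matrix(signals)) list(signals) else signals
  bank_list <- if (inherits(banks, "template_bank")) list(banks) else banks
  stopifnot(length(sig_list) == length(bank_list))
  agg <- if (combine == "mean") function(M) colMeans(M) else
    function(M) apply(M, 2, max)
  band_traces <- vector("list", length(sig_list))
  for (b in seq_along(sig_list)) {
    bank <- bank_list[[b]]
    tmpl <- bank$templates[[class]]
    if (is.null(tmpl)) stop("no template for class ", class)
    if (ncol(sig_list[[b]]) < bank$bin_smp + bank$offset_smp)
      stop("signal shorter than the template window")
    tr <- matrix(NA_real_, nrow(sig_list[[b]]), ncol(sig_list[[b]]))
    for (c in seq_len(nrow(sig_list[[b]]))) {
      r <- sliding_pearson(sig_list[[b]][c, ], tmpl[c, ],
                           bank$bin_smp, bank$offset_smp)
      tr[c, ] <- pmax(r, 0)
    }
    band_traces[[b]] <- tr
  }
  all_trace <- agg(do.call(rbind, band_traces))
  if (!by_band) return(all_trace)
  list(all = all_trace, band = lapply(band_traces, agg))
}

#' Predict a syllable onset from a confidence trace
#'
#' The predicted time is the argmax of the confidence within a window
#' (default 100 ms) centered on the stereotyped onset time; ties break
#' to the earliest sample.  Neither this predictor nor the baseline sees
#' the actual onset.
#'
#' @param conf confidence trace (0-based sample `t` at position
#'   `t + 1`).
#' @param stereotyped_sample stereotyped onset (0-based sample).
#' @param window_ms decision window width (default 100).
#' @param fs sampling rate (Hz).
#' @return list: `predicted` (0-based sample), `clipped` (logical: the
#'   window hit the trace bounds).
#' @export
predict_onset <- function(conf, stereotyped_sample, window_ms = 100,
                          fs = 1000) {
  half <- round(window_ms / 2 / 1000 * fs)
  lo <- round(stereotyped_sample) - half
  hi <- round(stereotyped_sample) + half
  clipped <- lo < 0 || hi > length(conf) - 1L
  lo <- max(lo, 0L); hi <- min(hi, length(conf) - 1L)
  w <- conf[(lo + 1L):(hi + 1L)]
  w[is.na(w)] <- -Inf
  list(predicted = lo + which.max(w) - 1L, clipped = clipped)
}

#' Stereotyped-behavior baseline prediction
#'
#' Training-set mean onset of the syllable relative to its motif's first
#' syllable, added to the test motif's actual first-syllable onset.
#'
#' @param train_rel training relative onsets (samples).
#' @param first_onset the test motif's first-syllable onset (samples).
#' @return predicted onset (samples, fractional).
#' @export
stereotyped_baseline <- function(train_rel, first_onset) {
  stopifnot(length(train_rel) >= 1)
  first_onset + mean(train_rel)
}

#' Compare neural and stereotyped onset predictions
#'
#' Paired, per syllable instance.  Two null hypotheses are tested on the
#' paired absolute errors: (1) the two predictors do not differ
#' (two-sided Wilcoxon signed-rank on the differences), and (2) the
#' neural predictor is not closer to the labeled onset (one-sided,
#' alternative: baseline error exceeds neural error).  Both must pass at
#' `p < 0.05` for the neural predictor to be called superior; BH across
#' the predictor family (the five bands plus the all-frequency
#' predictor, n = 6) is applied by the caller via `evaluate_predictions`
#' on the family table.
#'
#' @param neural_err,baseline_err paired signed errors
#'   (predicted - labeled, samples or ms).
#' @return list: `p_different`, `p_closer`, `median_neural`,
#'   `median_baseline`, `n`.
#' @export
prediction_tests <- function(neural_err, baseline_err) {
  stopifnot(length(neural_err) == length(baseline_err))
  d <- abs(baseline_err) - abs(neural_err)
  if (all(d == 0))
    return(list(p_different = NA_real_, p_closer = NA_real_,
                median_neural = stats::median(abs(neural_err)),
                median_baseline = stats::median(abs(baseline_err)),
                n = length(d)))
  p1 <- suppressWarnings(stats::wilcox.test(d)$p.value)
  p2 <- suppressWarnings(stats::wilcox.test(d, alternative = "greater")$p.value)
  list(p_different = p1, p_closer = p2,
       median_neural = stats::median(abs(neural_err)),
       median_baseline = stats::median(abs(baseline_err)),
       n = length(d))
}

#' BH correction over a family of onset predictors
#'
#' @param table data.frame with columns `p_different` and `p_closer`
#'   (one row per predictor, e.g. the five bands + all-frequency).
#' @param q FDR level (default 0.05).
#' @return the table with `q_different`, `q_closer` and `superior`
#'   (both tests pass at p < 0.05 and q < `q`).
#' @export
evaluate_predictions <- function(table, q = 0.05) {
  table$q_different <- stats::p.adjust(table$p_different, method = "BH")
  table$q_closer <- stats::p.adjust(table$p_closer, method = "BH")
  table$superior <- !is.na(table$p_different) &
    table$p_different < 0.05 & table$p_closer < 0.05 &
    table$q_different < q & table$q_closer < q
  table
}

#' Occurrence table of a branch (optional) syllable
#'
#' For every motif in a contextualized annotation set, reports whether
#' the branch syllable followed it, the motif's first-syllable onset
#' (anchor), the branch syllable's onset when it occurred, and the
#' omission type (`"skip"`: another motif followed without the note;
#' `"end_bout"`: the bout ended).
#'
#' @param ann a contextualized `annotation_set`.
#' @param branch_label the branch syllable's label (default "c").
#' @return data.frame: bout, motif, anchor, occurred, onset, type.
#' @export
branch_instances <- function(ann, branch_label = "c") {
  ev <- vocal_events(ann)
  firsts <- ev[!is.na(ev$first_in_motif) & ev$first_in_motif, ]
  out <- list()
  for (i in seq_len(nrow(firsts))) {
    b <- firsts$bout[i]; m <- firsts$motif[i]
    conn <- ev[ev$label == branch_label & !is.na(ev$motif) &
                 ev$bout == b & ev$motif == m, ]
    next_motif <- any(firsts$bout == b & firsts$motif == m + 1L)
    occurred <- nrow(conn) > 0
    out[[length(out) + 1L]] <- data.frame(
      bout = b, motif = m, anchor = firsts$onset[i],
      occurred = occurred,
      onset = if (occurred) conn$onset[1] else NA_real_,
      type = if (occurred) "occurred"
             else if (next_motif) "skip" else "end_bout")
  }
  do.call(rbind, out)
}

#' Branch-point (omitted-syllable) confidence analysis
#'
#' Splits the branch syllable's occurrences into stratified folds; per
#' fold, builds templates and the stereotyped time from the training
#' occurrences, then compares the maximum prediction confidence inside
#' the decision window (100 ms centered on the stereotyped time mapped
#' through each motif's anchor) between test-fold occurrences and
#' omission motifs (never in any training set) with a one-sided Welch
#' t-test (occurred > omitted).
#'
#' @param signals matrix or per-band list of causal feature signals.
#' @param instances output of [branch_instances()].
#' @param bin_ms,offset_ms feature window (ms); vectors are matched to
#'   the bands of `signals`.
#' @param fs sampling rate.
#' @param folds number of folds (default 5).
#' @param seed fold seed.
#' @param window_ms decision window (default 100).
#' @param pool_omissions treat skip and end-bout omissions as one
#'   distribution (default `TRUE`); `FALSE` returns per-type tests too.
#' @return list: data.frame `per_fold` (fold, t, p, n_occ, n_omit),
#'   optional `per_type`, and `windows` diagnostics.
#' @export
branch_analysis <- function(signals, instances, bin_ms = 100,
                            offset_ms = 10, fs = 1000, folds = 5,
                            seed = 1, window_ms = 100,
                            pool_omissions = TRUE) {
  occ <- instances[instances$occurred, ]
  omit <- instances[!instances$occurred, ]
  if (nrow(occ) < folds) stop("too few branch occurrences for the folds")
  set.seed(child_seed(seed, "branch-folds"))
  fold <- sample(rep_len(seq_len(folds), nrow(occ)))
  sig_list <- if (is.matrix(signals)) list(signals) else signals
  bin_ms <- rep_len(bin_ms, length(sig_list))
  offset_ms <- rep_len(offset_ms, length(sig_list))
  rows <- list(); type_rows <- list()
  for (f in seq_len(folds)) {
    tr <- occ[fold != f, ]; te <- occ[fold == f, ]
    if (nrow(te) < 2 || nrow(omit) < 2) {
      warning("fold ", f, " skipped: a condition has < 2 instances")
      next
    }
    rel <- round(mean(tr$onset - tr$anchor))
    banks <- lapply(seq_along(sig_list), function(b)
      build_templates(sig_list[[b]], list(branch = tr$onset),
                      bin_ms[b], offset_ms[b], fs))
    conf <- confidence_trace(if (length(sig_list) == 1L) sig_list[[1]]
                             else sig_list,
                             if (length(banks) == 1L) banks[[1]] else banks,
                             "branch")
    maxconf <- function(anchors) {
      vapply(anchors, function(a) {
        pr <- predict_onset(conf, a + rel, window_ms, fs)
        conf[pr$predicted + 1L]
      }, numeric(1))
    }
    co <- maxconf(te$anchor)
    cm <- maxconf(omit$anchor)
    ht <- stats::t.test(co, cm, alternative = "greater")
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f, t = unname(ht$statistic), p = ht$p.value,
      n_occ = length(co), n_omit = length(cm),
      mean_occ = mean(co), mean_omit = mean(cm))
    if (!pool_omissions) {
      for (ty in unique(omit$type)) {
        cmt <- cm[omit$type == ty]
        if (length(cmt) >= 2) {
          htt <- stats::t.test(co, cmt, alternative = "greater")
          type_rows[[length(type_rows) + 1L]] <- data.frame(
            fold = f, type = ty, t = unname(htt$statistic),
            p = htt$p.value)
        }
      }
    }
  }
  out <- list(per_fold = do.call(rbind, rows))
  if (!pool_omissions) out$per_type <- do.call(rbind, type_rows)
  out
}

#' Cross-validated onset prediction for one syllable class
#'
#' The complete per-syllable evaluation: stratified folds over the
#' syllable's instances; per fold, templates and the stereotyped onset
#' come from the training instances, and each test instance is predicted
#' both neurally (max confidence in the 100 ms window around the
#' stereotyped time) and by the stereotyped baseline.
#'
#' @param signals matrix or per-band list of causal feature signals.
#' @param onsets labeled onsets of the syllable (samples).
#' @param anchors first-syllable onsets of the containing motifs.
#' @param bin_ms,offset_ms feature window per band (scalars are
#'   recycled; vectors give each band its own window, e.g. from
#'   [onset_windows()]).
#' @param fs,folds,seed,window_ms as in [branch_analysis()].
#' @return data.frame per instance: fold, labeled, predicted, baseline,
#'   neural_err, baseline_err (samples), clipped.
#' @export
onset_prediction_cv <- function(signals, onsets, anchors, bin_ms = 100,
                                offset_ms = 10, fs = 1000, folds = 5,
                                seed = 1, window_ms = 100) {
  keep <- !is.na(anchors)
  onsets <- onsets[keep]; anchors <- anchors[keep]
  stopifnot(length(onsets) >= folds)
  set.seed(child_seed(seed, "onset-folds"))
  fold <- sample(rep_len(seq_len(folds), length(onsets)))
  sig_list <- if (is.matrix(signals)) list(signals) else signals
  bin_ms <- rep_len(bin_ms, length(sig_list))
  offset_ms <- rep_len(offset_ms, length(sig_list))
  rows <- list()
  for (f in seq_len(folds)) {
    tr <- fold != f
    rel <- onsets[tr] - anchors[tr]
    banks <- lapply(seq_along(sig_list), function(b)
      build_templates(sig_list[[b]], list(syl = onsets[tr]),
                      bin_ms[b], offset_ms[b], fs))
    conf <- confidence_trace(if (length(sig_list) == 1L) sig_list[[1]]
                             else sig_list,
                             if (length(banks) == 1L) banks[[1]] else banks,
                             "syl")
    for (i in which(!tr)) {
      stereo <- stereotyped_baseline(rel, anchors[i])
      pr <- predict_onset(conf, stereo, window_ms, fs)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, labeled = onsets[i], predicted = pr$predicted,
        baseline = stereo, neural_err = pr$predicted - onsets[i],
        baseline_err = stereo - onsets[i], clipped = pr$clipped)
    }
  }
  do.call(rbind, rows)
}
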