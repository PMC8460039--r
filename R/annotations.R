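# Behavioral annotation model: labeled intervals with bout/motif context.
#
# Conventions (used throughout the package):
#   * times are 0-based sample indices at the annotation sampling rate,
#     half-open intervals [onset, offset);
#   * silence carries two labels: "gap" for the short silences between
#     song elements, "silence" for non-song quiet inside a VAP;
#   * every other label is a vocal class (syllables "1","2",...; "i" for
#     introductory notes; connector/intra-motif notes; "call").

SILENCE_LABELS <- c("gap", "silence")

#' Construct an annotation set
#'
#' @param events data.frame with columns `label` (character), `onset`,
#'   `offset` (0-based sample indices, half-open); context columns
#'   (`bout`, `motif`, `first_in_motif`, `last_in_motif`, `first_motif`,
#'   `last_motif`, `flagged`) are added as `NA` if absent.
#' @param fs sampling rate (Hz) the sample indices refer to.
#' @param vaps optional data.frame of vocally-active-period bounds
#'   (`start`, `end`, samples).  When present every vocal event must lie
#'   inside exactly one VAP.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(events, fs, vaps = NULL) {
  stopifnot(is.data.frame(events),
            all(c("label", "onset", "offset") %in% names(events)), fs > 0)
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) && any(events$onset >= events$offset))
    stop("every event must satisfy onset < offset")
  for (col in c("bout", "motif")) {
    if (is.null(events[[col]])) events[[col]] <- NA_integer_
  }
  for (col in c("first_in_motif", "last_in_motif", "first_motif",
                "last_motif", "flagged")) {
    if (is.null(events[[col]])) events[[col]] <- NA
  }
  voc <- events[!(events$label %in% SILENCE_LABELS), , drop = FALSE]
  if (nrow(voc) > 1) {
    if (any(voc$onset[-1] < voc$offset[-nrow(voc)]))
      stop("overlapping vocal intervals")
  }
  if (!is.null(vaps) && nrow(voc)) {
    inside <- vapply(seq_len(nrow(voc)), function(i) {
      sum(voc$onset[i] >= vaps$start & voc$offset[i] <= vaps$end)
    }, integer(1))
    if (any(inside != 1L))
      stop("every vocal event must lie inside exactly one VAP")
  }
  structure(list(events = events, fs = fs, vaps = vaps),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  voc <- vocal_events(x)
  cat(sprintf("<annotation_set> %d events (%d vocal, %d classes) @ %g Hz, %s VAPs\n",
              nrow(x$events), nrow(voc), length(unique(voc$label)), x$fs,
              if (is.null(x$vaps)) "no" else nrow(x$vaps)))
  invisible(x)
}

#' Vocal (non-silence) events of an annotation set
#' @param ann an `annotation_set`.
#' @export
vocal_events <- function(ann) {
  ann$events[!(ann$events$label %in% SILENCE_LABELS), , drop = FALSE]
}

#' Group motif onsets into vocally active periods (VAPs)
#'
#' Consecutive onsets no more than `max_gap` seconds apart share a VAP
#' (the comparison is inclusive: a gap of exactly `max_gap` merges).
#' Each VAP is padded by `pad` seconds on both sides, floored at 0.
#'
#' @param motif_onsets numeric vector of motif onset times (seconds),
#'   sorted ascending.
#' @param max_gap merge threshold in seconds (default 20).
#' @param pad padding in seconds added before the first and after the
#'   last onset of each VAP (default 2).
#' @return data.frame with `start`, `end` (seconds) and `n_motifs`.
#' @export
group_vaps <- function(motif_onsets, max_gap = 20, pad = 2) {
  if (!length(motif_onsets))
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_motifs = integer(0)))
  if (is.unsorted(motif_onsets)) stop("motif onsets must be sorted")
  brk <- which(diff(motif_onsets) > max_gap)
  grp <- cumsum(c(1L, seq_along(motif_onsets)[-1] %in% (brk + 1L)))
  starts <- tapply(motif_onsets, grp, min) - pad
  ends <- tapply(motif_onsets, grp, max) + pad
  data.frame(start = pmax(0, unname(starts)), end = unname(ends),
             n_motifs = as.integer(table(grp)))
}

#' Add bout/motif context labels to hand annotations
#'
#' Reconstructs the bout and motif structure from the label sequence:
#' a new bout starts when the silent gap since the previous vocal event
#' exceeds `bout_gap` seconds; within a bout, motif index increments at
#' every occurrence of the first syllable of `motif_sequence`.  A bout
#' starts at the start of its first motif; introductory notes before the
#' first motif carry the bout index of the following bout with motif
#' index `NA`; intra-motif (connector) notes between motifs are assigned
#' to the preceding motif's context.  Syllables that cannot be placed in
#' any motif are flagged, not dropped.
#'
#' @param ann an `annotation_set`.
#' @param motif_sequence character vector: the stereotyped ordered
#'   syllable labels of one motif.
#' @param intro_label label used for introductory notes (default "i").
#' @param bout_gap silent gap (s) that separates bouts (default 1).
#' @return the annotation set with context columns filled.
#' @export
contextualize <- function(ann, motif_sequence, intro_label = "i",
                          bout_gap = 1) {
  ev <- ann$events
  vi <- which(!(ev$label %in% SILENCE_LABELS))
  if (!length(vi)) return(ann)
  on <- ev$onset[vi]; off <- ev$offset[vi]; lab <- ev$label[vi]
  gap_s <- c(Inf, (on[-1] - off[-length(off)]) / ann$fs)
  bout <- cumsum(gap_s > bout_gap)
  first_syl <- motif_sequence[1]
  motif <- rep(NA_integer_, length(vi))
  flagged <- rep(FALSE, length(vi))
  for (b in unique(bout)) {
    sel <- which(bout == b)
    m <- 0L
    for (j in sel) {
      if (lab[j] == first_syl) m <- m + 1L
      if (lab[j] == intro_label) {
        motif[j] <- NA_integer_            # intro: bout of what follows
      } else if (m == 0L) {
        motif[j] <- NA_integer_
        if (lab[j] %in% motif_sequence) flagged[j] <- TRUE
      } else {
        motif[j] <- m                       # connectors inherit preceding
      }
    }
  }
  first_in_motif <- lab == first_syl & !is.na(motif)
  last_syl <- motif_sequence[length(motif_sequence)]
  last_in_motif <- lab == last_syl & !is.na(motif)
  n_motifs <- stats::ave(ifelse(is.na(motif), 0L, motif), bout,
                         FUN = function(x) max(x, 0L))
  first_motif <- !is.na(motif) & motif == 1L
  last_motif <- !is.na(motif) & motif == n_motifs
  ev$bout[vi] <- bout
  ev$motif[vi] <- motif
  ev$first_in_motif[vi] <- first_in_motif
  ev$last_in_motif[vi] <- last_in_motif
  ev$first_motif[vi] <- first_motif
  ev$last_motif[vi] <- last_motif
  ev$flagged[vi] <- flagged
  annotation_set(ev, ann$fs, ann$vaps)
}

#' Event sets: one class with its alignment times
#'
#' @param class class label.
#' @param times alignment sample indices.
#' @param anchors optional per-event motif anchor (onset of the first
#'   syllable of the containing motif).
#' @export
event_set <- function(class, times, anchors = rep(NA_real_, length(times))) {
  structure(list(class = class, times = as.numeric(times),
                 anchors = as.numeric(anchors)),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> class '%s', n = %d\n", x$class, length(x$times)))
  invisible(x)
}

#' Select and balance events across classes
#'
#' Selects alignment (onset) times for each requested class, balanced to
#' a common count by seeded uniform subsampling without replacement.
#' When `n_per_class` is absent the minimum class count is used.  The
#' pseudo-class `"silence"` is sampled as time points centered within
#' silent spans of at least `min_silence` seconds inside VAPs.
#'
#' @param ann a contextualized `annotation_set`.
#' @param classes character vector of class labels (may include
#'   `"silence"`).
#' @param n_per_class optional count per class.
#' @param seed integer seed for the subsampling.
#' @param min_silence minimum silent-span length (s) eligible for silence
#'   events (default 2).
#' @return named list of [event_set()] objects.
#' @export
select_and_balance <- function(ann, classes, n_per_class = NULL, seed = 1,
                               min_silence = 2) {
  ev <- vocal_events(ann)
  cand <- list()
  for (cl in classes) {
    if (cl == "silence") {
      sp <- silent_spans(ann, min_silence)
      cand[[cl]] <- event_set("silence", (sp$start + sp$end) / 2)
    } else {
      sel <- ev[ev$label == cl, , drop = FALSE]
      if (!nrow(sel)) stop("class has no instances: ", cl)
      anch <- rep(NA_real_, nrow(sel))
      if (!all(is.na(sel$motif))) {
        firsts <- ev[!is.na(ev$first_in_motif) & ev$first_in_motif, ]
        key <- paste(sel$bout, sel$motif)
        fkey <- paste(firsts$bout, firsts$motif)
        anch <- firsts$onset[match(key, fkey)]
      }
      cand[[cl]] <- event_set(cl, sel$onset, anch)
    }
  }
  counts <- vapply(cand, function(e) length(e$times), integer(1))
  n <- if (is.null(n_per_class)) min(counts) else n_per_class
  short <- names(counts)[counts < n]
  if (length(short))
    stop("requested n exceeds the count of class: ",
         paste(short, collapse = ", "))
  set.seed(child_seed(seed, "balance"))
  lapply(cand, function(e) {
    keep <- sort(sample.int(length(e$times), n))
    event_set(e$class, e$times[keep], e$anchors[keep])
  })
}

#' Silent spans inside the VAPs of an annotation set
#' @param ann an `annotation_set` (VAPs required; if absent the full
#'   recording extent is used).
#' @param min_len minimum span length in seconds.
#' @return data.frame `start`, `end` in samples.
#' @export
silent_spans <- function(ann, min_len = 2) {
  voc <- vocal_events(ann)
  vaps <- ann$vaps
  if (is.null(vaps)) {
    vaps <- data.frame(start = 0, end = max(voc$offset) + ann$fs)
  }
  out <- list()
  for (i in seq_len(nrow(vaps))) {
    v <- voc[voc$onset < vaps$end[i] & voc$offset > vaps$start[i], ]
    if (nrow(v)) {
      starts <- c(vaps$start[i], v$offset)
      ends <- c(v$onset, vaps$end[i])
    } else {
      starts <- vaps$start[i]; ends <- vaps$end[i]
    }
    keep <- (ends - starts) / ann$fs >= min_len
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(start = starts[keep],
                                            end = ends[keep])
  }
  if (!length(out)) return(data.frame(start = numeric(0), end = numeric(0)))
  do.call(rbind, out)
}

#' Export the contextualized event table as CSV
#'
#' @param ann an `annotation_set`.
#' @param path output path.
#' @export
write_event_table <- function(ann, path) {
  ev <- ann$events
  out <- data.frame(label = ev$label,
                    onset_ms = ev$onset / ann$fs * 1000,
                    offset_ms = ev$offset / ann$fs * 1000,
                    bout = ev$bout, motif = ev$motif,
                    first_in_motif = ev$first_in_motif,
                    last_in_motif = ev$last_in_motif,
                    first_motif = ev$first_motif,
                    last_motif = ev$last_motif,
                    flagged = ev$flagged)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
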