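# Song grammar: states, transition probabilities, timing distributions.

#' Construct a song grammar
#'
#' Describes zebra finch song structure as a small stochastic grammar:
#' a fixed motif (an ordered syllable sequence), a branch point at the
#' end of each motif (continue to another motif, insert an intra-motif
#' "connector" note, or end the bout), a variable number of introductory
#' notes before the first motif, and per-element timing jitter.
#'
#' @param motif ordered character vector of syllable labels forming one
#'   motif.
#' @param syllable_ms named numeric: mean duration (ms) per syllable
#'   label (must cover `motif`, the connector and the intro note).
#' @param syllable_jitter_ms duration jitter SD (ms), one value recycled.
#' @param gap_ms mean silent gap between song elements (ms).
#' @param gap_jitter_ms onset jitter SD (ms): within a motif every
#'   element's onset jitters independently around the stereotyped
#'   schedule (clock-anchored timing; errors do not accumulate across
#'   the motif, matching the tight tempo regulation of zebra finch
#'   song).  Between motifs and around intro notes/calls the same SD
#'   applies to the silent gaps.
#' @param branch named numeric: probabilities at the end-of-motif branch
#'   point, names `connector` (insert intra-motif note then a new motif),
#'   `continue` (new motif directly), `end` (end the bout).  Must sum
#'   to 1.
#' @param connector_label label of the intra-motif note.
#' @param connector_extra_gap_ms additional silent gap before a
#'   connector note (default 40 ms): branch points carry a longer
#'   latency than the obligatory within-motif transitions.
#' @param intro_label label of the introductory note.
#' @param intro_count_probs probabilities of 0,1,2,... introductory notes
#'   before the first motif.
#' @param call_prob probability that a lone call is appended after a
#'   bout, inside the VAP.
#' @param interbout_silence_s `c(min, mean_extra)`: inter-bout silence is
#'   `min + Exp(mean_extra)` seconds.
#' @param min_gap_ms floor for jittered gaps (ms).
#' @return an object of class `song_grammar`.
#' @export
song_grammar <- function(motif = as.character(1:5),
                         syllable_ms = c("1" = 80, "2" = 85, "3" = 100,
                                         "4" = 90, "5" = 70, "c" = 60,
                                         "i" = 40, "call" = 50),
                         syllable_jitter_ms = 5,
                         gap_ms = 100,
                         gap_jitter_ms = 15,
                         branch = c(connector = 0.5, continue = 0.2,
                                    end = 0.3),
                         connector_label = "c",
                         connector_extra_gap_ms = 40,
                         intro_label = "i",
                         intro_count_probs = c(0.1, 0.3, 0.4, 0.2),
                         call_prob = 0.15,
                         interbout_silence_s = c(3, 1.5),
                         min_gap_ms = 5) {
  stopifnot(length(motif) >= 1,
            all(motif %in% names(syllable_ms)),
            connector_label %in% names(syllable_ms),
            intro_label %in% names(syllable_ms),
            all(syllable_ms > 0), gap_ms > 0,
            all(names(branch) == c("connector", "continue", "end")))
  if (abs(sum(branch) - 1) > 1e-9)
    stop("branch probabilities must sum to 1")
  if (branch[["end"]] <= 0)
    stop("non-terminating grammar: end-of-bout probability must be > 0")
  if (abs(sum(intro_count_probs) - 1) > 1e-9)
    stop("intro note count probabilities must sum to 1")
  structure(list(motif = motif, syllable_ms = syllable_ms,
                 syllable_jitter_ms = syllable_jitter_ms,
                 gap_ms = gap_ms, gap_jitter_ms = gap_jitter_ms,
                 branch = branch, connector_label = connector_label,
                 connector_extra_gap_ms = connector_extra_gap_ms,
                 intro_label = intro_label,
                 intro_count_probs = intro_count_probs,
                 call_prob = call_prob,
                 interbout_silence_s = interbout_silence_s,
                 min_gap_ms = min_gap_ms),
            class = "song_grammar")
}

#' @export
print.song_grammar <- function(x, ...) {
  cat(sprintf("<song_grammar> motif %s; branch c=%.2f/cont=%.2f/end=%.2f\n",
              paste(x$motif, collapse = "-"), x$branch[["connector"]],
              x$branch[["continue"]], x$branch[["end"]]))
  invisible(x)
}

#' Sample annotated song behavior from a grammar
#'
#' Generates `n_bouts` bouts of song: introductory notes, motif
#' repetitions with jittered durations and gaps, optional connector notes
#' at the motif branch point, occasional calls, and the two silence
#' labels ("gap" within song, "silence" between bouts inside the VAP).
#' Identical `(grammar, n_bouts, seed)` give bitwise-identical output.
#'
#' @param grammar a [song_grammar()].
#' @param n_bouts number of bouts, `>= 1`.
#' @param seed integer seed.
#' @param fs sampling rate (Hz) for event sample indices (default 1000).
#' @return an `annotation_set` with ground-truth context columns filled
#'   and VAPs computed via [group_vaps()].
#' @export
sample_behavior <- function(grammar, n_bouts, seed, fs = 1000) {
  stopifnot(inherits(grammar, "song_grammar"), n_bouts >= 1)
  set.seed(child_seed(seed, "behavior"))
  g <- grammar
  dur <- function(lab) {
    max(g$min_gap_ms,
        stats::rnorm(1, g$syllable_ms[[lab]], g$syllable_jitter_ms)) / 1000
  }
  gap <- function() {
    max(g$min_gap_ms, stats::rnorm(1, g$gap_ms, g$gap_jitter_ms)) / 1000
  }
  rows <- list()
  t <- 2.0                                  # lead-in silence (s)
  motif_onsets <- numeric(0)
  add <- function(label, t0, t1, bout, motif) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, onset = round(t0 * fs), offset = round(t1 * fs),
      bout = bout, motif = motif)
  }
  for (b in seq_len(n_bouts)) {
    n_intro <- sample.int(length(g$intro_count_probs), 1,
                          prob = g$intro_count_probs) - 1L
    for (k in seq_len(n_intro)) {
      d <- dur(g$intro_label)
      add(g$intro_label, t, t + d, b, NA_integer_)
      t <- t + d + gap()
    }
    # clock-anchored motif timing: each element's onset jitters
    # independently around the stereotyped schedule (motifs are tightly
    # tempo-regulated; timing errors do not accumulate across the motif)
    nominal <- cumsum(c(0, (g$syllable_ms[g$motif] + g$gap_ms) / 1000))
    m <- 0L
    repeat {
      m <- m + 1L
      t_anchor <- t
      prev_off <- -Inf
      for (k in seq_along(g$motif)) {
        s <- g$motif[k]
        jit <- if (k == 1) 0 else
          stats::rnorm(1, 0, g$gap_jitter_ms) / 1000
        on_t <- max(t_anchor + nominal[k] + jit,
                    prev_off + g$min_gap_ms / 1000)
        d <- dur(s)
        if (k == 1) motif_onsets <- c(motif_onsets, on_t)
        add(s, on_t, on_t + d, b, m)
        prev_off <- on_t + d
      }
      t <- prev_off + gap()
      br <- sample(names(g$branch), 1, prob = g$branch)
      if (br == "connector") {
        # the connector also sits at a stereotyped offset from the
        # motif start, with the same independent onset jitter
        on_t <- max(t_anchor + nominal[length(g$motif) + 1L] +
                      g$connector_extra_gap_ms / 1000 +
                      stats::rnorm(1, 0, g$gap_jitter_ms) / 1000,
                    prev_off + g$min_gap_ms / 1000)
        d <- dur(g$connector_label)
        add(g$connector_label, on_t, on_t + d, b, m)
        t <- on_t + d + gap()
      } else if (br == "end") break
    }
    if (stats::runif(1) < g$call_prob) {
      # keep the call inside the VAP padding that follows the last motif
      t <- t + stats::runif(1, 0.3, 0.9)
      d <- dur("call")
      add("call", t, t + d, b, NA_integer_)
    }
    t <- t + g$interbout_silence_s[1] + stats::rexp(1, 1 / g$interbout_silence_s[2])
  }
  ev <- do.call(rbind, rows)
  # context flags from ground truth
  ev$first_in_motif <- ev$label == g$motif[1] & !is.na(ev$motif)
  ev$last_in_motif <- ev$label == g$motif[length(g$motif)] & !is.na(ev$motif)
  nmax <- stats::ave(ifelse(is.na(ev$motif), 0L, ev$motif), ev$bout,
                     FUN = max)
  ev$first_motif <- !is.na(ev$motif) & ev$motif == 1L
  ev$last_motif <- !is.na(ev$motif) & ev$motif == nmax
  ev$flagged <- FALSE
  # silence labels: "gap" between consecutive vocal events within a bout,
  # "silence" between bouts (within the VAP)
  sil <- list()
  for (i in seq_len(nrow(ev) - 1L)) {
    a <- ev$offset[i]; bnx <- ev$onset[i + 1L]
    if (bnx <= a) next
    lab <- if (ev$bout[i + 1L] == ev$bout[i]) "gap" else "silence"
    sil[[length(sil) + 1L]] <- data.frame(
      label = lab, onset = a, offset = bnx, bout = NA_integer_,
      motif = NA_integer_, first_in_motif = NA, last_in_motif = NA,
      first_motif = NA, last_motif = NA, flagged = FALSE)
  }
  if (length(sil)) ev <- rbind(ev, do.call(rbind, sil))
  vaps_s <- group_vaps(motif_onsets)
  vaps <- data.frame(start = round(vaps_s$start * fs),
                     end = round(vaps_s$end * fs))
  annotation_set(ev, fs, vaps)
}
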