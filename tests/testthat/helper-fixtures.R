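# Shared fixtures built in code.

# Deterministic grammar: no jitter, no intro notes, no connector, one
# motif per bout.  Every bout is an identical copy of the motif.
deterministic_grammar <- function() {
  song_grammar(syllable_jitter_ms = 0, gap_jitter_ms = 0,
               branch = c(connector = 0, continue = 0, end = 1),
               intro_count_probs = 1, call_prob = 0)
}

# Small default-style dataset used by several suites (kept small: 8
# bouts, 4 channels).
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- song_grammar()
      ann <- sample_behavior(g, 8, seed = 101)
      m <- lfp_model(c(g$motif, "c", "i"), channel_count = 4, seed = 101)
      cache <<- list(grammar = g, ann = ann, model = m,
                     rec = synthesize_lfp(ann, m))
    }
    cache
  }
})

# toy recording: pure sinusoids per channel
sine_recording <- function(freqs, fs = 1000, dur = 4, amp = 1) {
  t <- seq_len(dur * fs) / fs
  v <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t),
                numeric(length(t))))
  recording(v, fs)
}
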