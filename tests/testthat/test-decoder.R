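# Template features and LDA classification.

test_that("templates are training-set means with window checks", {
  sig <- matrix(seq_len(2000), nrow = 2, byrow = TRUE)
  bank1 <- build_templates(sig, list(A = 500), bin_ms = 100,
                           offset_ms = 10, fs = 1000)
  # single instance: template equals that trace
  idx <- (500 - 10 - 100 + 1):(500 - 10)
  expect_equal(bank1$templates$A[1, ], sig[1, idx])
  # x and -x average to zero
  sig2 <- rbind(sin(1:1000 / 5), sin(1:1000 / 5))
  b2 <- build_templates(sig2, list(A = c(500, 500)), 50, 10, 1000)
  b2b <- build_templates(-sig2, list(A = c(500, 500)), 50, 10, 1000)
  expect_equal(b2$templates$A + b2b$templates$A,
               matrix(0, 2, 50))
  # collision with recording start is dropped and counted
  b3 <- build_templates(sig, list(A = c(50, 500)), 100, 10, 1000)
  expect_equal(b3$n_dropped, 1L)
  expect_equal(b3$templates$A[1, ], sig[1, idx])
})

test_that("template converges to the waveform as instances accumulate", {
  set.seed(6)
  fs <- 1000
  wf <- sin(2 * pi * 30 * (1:100) / fs)
  n_inst <- c(4, 64)
  errs <- vapply(n_inst, function(m) {
    onsets <- seq(500, by = 400, length.out = m)
    n <- max(onsets) + 200
    x <- rnorm(n)
    for (o in onsets) x[(o - 110 + 1):(o - 10)] <- wf + rnorm(100)
    bank <- build_templates(matrix(x, 1), list(A = onsets), 100, 10, fs)
    sqrt(mean((bank$templates$A[1, ] - wf)^2))
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 2)   # RMS error shrinks like 1/sqrt(N)
})

test_that("pearson features are bounded with zero-variance guard", {
  tm <- sin(1:50 / 3)
  expect_equal(pearson_feature(tm, tm), 1)
  expect_equal(pearson_feature(-tm, tm), -1)
  expect_equal(pearson_feature(rep(2, 50), tm), 0)
  expect_error(pearson_feature(tm[1:10], tm), "lengths differ")
  # orthogonal equal-power noise halves the correlation (on average)
  set.seed(7)
  r <- replicate(100, {
    noise <- rnorm(50, sd = sd(tm))
    pearson_feature(tm + noise, tm)
  })
  expect_lt(abs(mean(r) - 1 / sqrt(2)), 0.1)
})

test_that("binomial chance level matches its definition", {
  # exhaustive check against the tail probability
  for (N in c(50, 686)) {
    for (k in c(2, 7)) {
      ch <- binomial_chance(N, k)
      m <- ch * N
      expect_lt(pbinom(m - 1, N, 1 / k, lower.tail = FALSE), 0.05)
      expect_gte(pbinom(m - 2, N, 1 / k, lower.tail = FALSE), 0.05)
    }
  }
})

make_sep_events <- function(n_per = 20, fs = 1000) {
  # two classes with linearly separable pre-onset waveforms
  set.seed(20)
  onsA <- seq(1000, by = 500, length.out = n_per)
  onsB <- seq(1000 + 250, by = 500, length.out = n_per)
  n <- max(onsB) + 500
  x <- 0.1 * rnorm(n)
  wfA <- sin(2 * pi * 30 * (1:100) / fs)
  wfB <- sin(2 * pi * 30 * (1:100) / fs + pi)
  for (o in onsA) x[(o - 110 + 1):(o - 10)] <- x[(o - 110 + 1):(o - 10)] + wfA
  for (o in onsB) x[(o - 110 + 1):(o - 10)] <- x[(o - 110 + 1):(o - 10)] + wfB
  list(sig = matrix(x, 1),
       sets = list(A = event_set("A", onsA), B = event_set("B", onsB)))
}

test_that("separable classes hit perfect accuracy; shuffled labels sit at chance", {
  d <- make_sep_events()
  rep_ <- classify_events(d$sig, d$sets, bin_ms = 100, offset_ms = 10)
  expect_equal(rep_$fold_accuracy, rep(1, 5))

  # permute labels: accuracy within the binomial chance band
  set.seed(21)
  all_t <- c(d$sets$A$times, d$sets$B$times)
  perm <- sample(all_t)
  sets_p <- list(A = event_set("A", perm[1:20]),
                 B = event_set("B", perm[21:40]))
  rep_p <- classify_events(d$sig, sets_p, bin_ms = 100, offset_ms = 10)
  band <- qbinom(c(0.005, 0.995), 40, 0.5) / 40
  expect_gte(rep_p$accuracy, band[1])
  expect_lte(rep_p$accuracy, band[2])
})

test_that("no training/test leakage: deleting a test event leaves fold templates unchanged", {
  d <- make_sep_events()
  labels <- rep(c("A", "B"), each = 20)
  onsets <- c(d$sets$A$times, d$sets$B$times)
  fold <- songlfp:::stratified_folds(labels, 5, seed = 1)
  f <- 1
  tr <- fold != f
  bank_full <- build_templates(d$sig, split(onsets[tr], labels[tr]),
                               100, 10, 1000)
  # drop one *test* event; training events unchanged
  drop_idx <- which(!tr)[1]
  keep <- setdiff(seq_along(onsets), drop_idx)
  bank_dropped <- build_templates(d$sig,
                                  split(onsets[keep][fold[keep] != f],
                                        labels[keep][fold[keep] != f]),
                                  100, 10, 1000)
  expect_identical(bank_full$templates, bank_dropped$templates)
})

test_that("hyperparameter search finds pre-onset information and breaks ties", {
  d <- make_sep_events()
  hs <- hyperparameter_search(d$sig, d$sets, bin_widths = c(50, 100),
                              offsets = c(10, 150))
  # information lives in [-110, -10): offset 150 misses it entirely
  best <- hs$best
  expect_equal(best$offset_ms, 10)
  expect_true(all(hs$grid$accuracy[hs$grid$offset_ms == 10] >=
                    hs$grid$accuracy[hs$grid$offset_ms == 150]))
  # tie-break: among equal accuracies prefer the smaller bin width
  g <- data.frame(bin_ms = c(100, 50), offset_ms = c(10, 10),
                  accuracy = c(1, 1))
  ord <- order(-g$accuracy, g$bin_ms, g$offset_ms)
  expect_equal(g$bin_ms[ord[1]], 50)
  expect_error(hyperparameter_search(d$sig, d$sets, bin_widths = c(),
                                     offsets = c(10)), "empty grid")
})

test_that("channel adding is flat for duplicated channels, grows for complementary ones", {
  d <- make_sep_events()
  sig2 <- rbind(d$sig, d$sig)        # identical copies
  curve <- channel_adding(sig2, d$sets, n_reps = 3, bin_ms = 100,
                          offset_ms = 10)
  expect_equal(curve$mean_accuracy[1], curve$mean_accuracy[2],
               tolerance = 0.05)

  # complementary channels: each carries one class's waveform
  set.seed(22)
  n <- ncol(d$sig)
  x2 <- 0.4 * rnorm(n)
  wfB <- sin(2 * pi * 18 * (1:100) / 1000)
  for (o in d$sets$B$times)
    x2[(o - 110 + 1):(o - 10)] <- x2[(o - 110 + 1):(o - 10)] + wfB
  noisy1 <- d$sig + 0.4 * rnorm(n)
  curve2 <- channel_adding(rbind(noisy1, x2), d$sets, n_reps = 6,
                           bin_ms = 100, offset_ms = 10)
  expect_gte(curve2$mean_accuracy[2] + 0.02, curve2$mean_accuracy[1])
})

test_that("phase-only and power-only ablations dissociate by construction", {
  # wide gaps isolate each syllable: no sequence-context leak into the
  # feature window, so amplitude is genuinely uninformative
  g <- song_grammar(syllable_jitter_ms = 0, gap_jitter_ms = 0,
                    gap_ms = 350,
                    branch = c(connector = 0, continue = 0, end = 1),
                    intro_count_probs = 1, call_prob = 0)
  ann <- sample_behavior(g, 22, seed = 31)
  # classes differ ONLY in onset phase: no class templates, no envelope
  pref <- matrix(seq(0, 2 * pi * 4 / 5, length.out = 5), ncol = 1)
  rownames(pref) <- g$motif
  m <- lfp_model(g$motif,
                 bands = data.frame(low = 25, high = 35, amplitude = 1,
                                    kappa = Inf),
                 preferred_phase = pref, channel_count = 2,
                 background_sd = 0.3, template_snr = 0, seed = 31)
  m$class_envelopes <- lapply(m$class_envelopes, function(e) {
    e$depth <- 0; e
  })
  rec <- synthesize_lfp(ann, m)
  annc <- contextualize(ann, g$motif)
  sets <- select_and_balance(annc, g$motif, seed = 1)
  res <- ablate(rec, sets, band = c(25, 35), bin_ms = 100, offset_ms = 10)
  expect_gt(res$phase_only$accuracy, res$phase_only$chance)
  # power carries nothing: accuracy within the chance band
  n <- res$power_only$n_events
  band <- qbinom(0.999, n, 1 / 5) / n
  expect_lte(res$power_only$accuracy, band)
  # "both" does not fall below the informative mode by more than one SD
  expect_gte(res$both$accuracy,
             res$phase_only$accuracy - res$phase_only$sd - 0.05)
})

test_that("amplitude-only classes invert the ablation", {
  g <- deterministic_grammar()
  ann <- sample_behavior(g, 24, seed = 32)
  m <- lfp_model(g$motif,
                 bands = data.frame(low = 25, high = 35, amplitude = 1,
                                    kappa = 0),   # random phases
                 channel_count = 2, background_sd = 0.3,
                 template_snr = 0, seed = 32)
  # deep class-specific envelopes carry the information
  depths <- seq(0.2, 1.8, length.out = 5)
  for (i in seq_along(m$class_envelopes)) {
    m$class_envelopes[[i]]$depth <- depths[i]
    m$class_envelopes[[i]]$center_s <- -0.05
    m$class_envelopes[[i]]$width_s <- 0.02 + 0.015 * i
  }
  rec <- synthesize_lfp(ann, m)
  annc <- contextualize(ann, g$motif)
  sets <- select_and_balance(annc, g$motif, seed = 1)
  res <- ablate(rec, sets, band = c(25, 35), bin_ms = 100, offset_ms = 10)
  expect_gt(res$power_only$accuracy, res$power_only$chance)
  expect_gte(res$both$accuracy,
             res$power_only$accuracy - res$power_only$sd - 0.05)
})

test_that("permuted-label accuracy rarely beats the binomial chance bar", {
  d <- make_sep_events()
  all_t <- sort(c(d$sets$A$times, d$sets$B$times))
  set.seed(33)
  hits <- 0; runs <- 60
  for (i in seq_len(runs)) {
    perm <- sample(all_t)
    sets_p <- list(A = event_set("A", perm[1:20]),
                   B = event_set("B", perm[21:40]))
    rep_p <- classify_events(d$sig, sets_p, bin_ms = 100, offset_ms = 10,
                             seed = i)
    if (rep_p$accuracy > rep_p$chance) hits <- hits + 1
  }
  expect_lt(hits / runs, 0.05 + 2 * sqrt(0.05 * 0.95 / runs))
})
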