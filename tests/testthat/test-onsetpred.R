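# Template-matching onset prediction.

test_that("confidence trace clips negatives and peaks at a planted template", {
  fs <- 1000
  set.seed(40)
  n <- 4000
  x <- 0.05 * rnorm(n)
  tmpl_wave <- sin(2 * pi * 30 * (1:100) / fs)
  t_star <- 2000                      # 0-based onset of the planted event
  idx <- (t_star - 110 + 1):(t_star - 10)
  x[idx] <- tmpl_wave
  sig <- matrix(x, 1)
  bank <- build_templates(sig, list(syl = t_star), 100, 10, fs)
  conf <- confidence_trace(sig, bank, "syl")
  expect_true(all(conf >= 0 & conf <= 1, na.rm = TRUE))
  expect_equal(which.max(conf) - 1L, t_star)
  expect_equal(max(conf, na.rm = TRUE), 1, tolerance = 1e-9)
  # all-negative correlations give a zero trace
  bank_neg <- bank
  bank_neg$templates$syl <- -bank$templates$syl
  segs <- confidence_trace(sig, bank_neg, "syl")
  expect_equal(segs[t_star + 1L], 0)
})

test_that("confidence is causal: future samples never change it", {
  fs <- 1000
  set.seed(41)
  x <- rnorm(3000)
  sig <- matrix(x, 1)
  bank <- build_templates(sig, list(syl = 1500), 100, 20, fs)
  conf1 <- confidence_trace(sig, bank, "syl")
  # zero everything at/after labeled onset - offset
  x2 <- x; x2[(1500 - 20 + 1):3000] <- 0
  conf2 <- confidence_trace(matrix(x2, 1), bank, "syl")
  expect_equal(conf1[1500 + 1L], conf2[1500 + 1L], tolerance = 1e-12)
})

test_that("matched motifs beat phase-shuffled surrogates", {
  fs <- 1000
  set.seed(42)
  wf <- sin(2 * pi * 30 * (1:100) / fs) * songlfp:::tukey_window(100, 1)
  motif <- 0.3 * rnorm(1200)
  motif[501:600] <- motif[501:600] + wf
  sig <- matrix(motif, 1)
  bank <- build_templates(sig, list(syl = 610), 100, 10, fs)
  real_max <- max(confidence_trace(sig, bank, "syl"), na.rm = TRUE)
  n_higher <- 0
  for (i in 1:50) {
    X <- fft(motif)
    ph <- runif(length(X), 0, 2 * pi)
    ph[1] <- 0
    half <- 2:(length(X) / 2)
    ph[length(X) + 2 - half] <- -ph[half]
    surr <- Re(fft(Mod(X) * exp(1i * ph), inverse = TRUE)) / length(X)
    smax <- max(confidence_trace(matrix(surr, 1), bank, "syl"),
                na.rm = TRUE)
    if (smax >= real_max) n_higher <- n_higher + 1
  }
  expect_lt(n_higher / 50, 0.05)
})

test_that("onset prediction takes the window argmax with earliest tie-break", {
  conf <- rep(0, 1000)
  conf[601] <- 1                      # 0-based sample 600
  pr <- predict_onset(conf, stereotyped_sample = 580)
  expect_equal(pr$predicted, 600)
  expect_false(pr$clipped)
  # flat trace: earliest sample of the window
  pr2 <- predict_onset(rep(0.5, 1000), 500)
  expect_equal(pr2$predicted, 450)
  # clipping flagged at trace edges
  pr3 <- predict_onset(rep(0, 200), 10)
  expect_true(pr3$clipped)
})

test_that("stereotyped baseline is the training mean offset", {
  expect_equal(stereotyped_baseline(c(100, 110, 120), 5000), 5110)
  # zero-jitter: baseline error identically zero
  g <- deterministic_grammar()
  ann <- sample_behavior(g, 6, seed = 50)
  annc <- contextualize(ann, g$motif)
  ev <- vocal_events(annc)
  s3 <- ev[ev$label == "3", ]
  firsts <- ev[!is.na(ev$first_in_motif) & ev$first_in_motif, ]
  anchor <- firsts$onset[match(paste(s3$bout, s3$motif),
                               paste(firsts$bout, firsts$motif))]
  rel <- s3$onset - anchor
  pred <- stereotyped_baseline(rel[1:4], anchor[5])
  expect_equal(pred, s3$onset[5])
})

test_that("baseline errors follow the programmed onset jitter", {
  g <- song_grammar(gap_jitter_ms = 15, syllable_jitter_ms = 0,
                    branch = c(connector = 0, continue = 0, end = 1),
                    intro_count_probs = 1, call_prob = 0)
  ann <- sample_behavior(g, 200, seed = 51)
  annc <- contextualize(ann, g$motif)
  ev <- vocal_events(annc)
  s2 <- ev[ev$label == "2", ]
  firsts <- ev[!is.na(ev$first_in_motif) & ev$first_in_motif, ]
  anchor <- firsts$onset[match(paste(s2$bout, s2$motif),
                               paste(firsts$bout, firsts$motif))]
  err <- (s2$onset - anchor) - mean(s2$onset - anchor)
  # syllable-2 onset jitter = one jittered gap (SD 15 ms, floor at 5 ms)
  expect_equal(sd(err), 15, tolerance = 3)
  expect_equal(median(abs(err)), 15 * qnorm(0.75), tolerance = 3.5)
})

test_that("two-test evaluation and BH behave on known inputs", {
  # identical errors: non-significant
  r0 <- prediction_tests(rep(3, 30), rep(3, 30))
  expect_true(is.na(r0$p_different))
  # neural errors stochastically half the baseline: both tests pass
  set.seed(52)
  base <- rnorm(50, 0, 20)
  neur <- base / 2 + rnorm(50, 0, 1)
  r1 <- prediction_tests(neur, base)
  expect_lt(r1$p_different, 0.05)
  expect_lt(r1$p_closer, 0.05)
  # BH step-up: one strong effect among six survives
  tab <- data.frame(p_different = c(0.001, runif(5, 0.3, 0.9)),
                    p_closer = c(0.001, runif(5, 0.3, 0.9)))
  res <- evaluate_predictions(tab)
  expect_true(res$superior[1])
  expect_false(any(res$superior[-1]))
})

test_that("branch instances classify occurrence and omission types", {
  g <- song_grammar(branch = c(connector = 0.5, continue = 0.2,
                               end = 0.3), call_prob = 0)
  ann <- sample_behavior(g, 40, seed = 53)
  annc <- contextualize(ann, g$motif)
  bi <- branch_instances(annc)
  ev <- vocal_events(annc)
  expect_equal(sum(bi$occurred), sum(ev$label == "c"))
  expect_setequal(unique(bi$type), c("occurred", "skip", "end_bout"))
  # every motif accounted for exactly once
  firsts <- ev[!is.na(ev$first_in_motif) & ev$first_in_motif, ]
  expect_equal(nrow(bi), nrow(firsts))
})

test_that("identical confidence distributions give p near 0.5", {
  set.seed(54)
  co <- rnorm(20, 0.5, 0.1); cm <- rnorm(20, 0.5, 0.1)
  ht <- t.test(co, cm, alternative = "greater")
  expect_gt(ht$p.value, 0.05)
})
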