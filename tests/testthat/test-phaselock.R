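# ITPC, Rayleigh statistics, sustained Z, alignment contrast.

test_that("itpc matches closed-form values", {
  expect_equal(itpc(rep(1.3, 20))$r, 1)
  expect_equal(itpc(c(0, pi))$r, 0)
  expect_equal(itpc(c(0, pi / 2))$r, 1 / sqrt(2), tolerance = 1e-12)
})

test_that("itpc is rotation invariant and handles missing phases", {
  set.seed(9)
  ph <- matrix(runif(60, -pi, pi), nrow = 6)
  a <- itpc(ph)
  b <- itpc(songlfp:::wrap_angle(ph + 1.1))
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(songlfp:::wrap_angle(b$mean_angle - a$mean_angle),
               rep(1.1, 10), tolerance = 1e-9)
  ph[2, 3] <- NaN
  cc <- itpc(ph)
  expect_equal(cc$n[3], 5)
  expect_true(cc$flagged[3])
  expect_false(any(cc$flagged[-3]))
})

test_that("rayleigh p follows the asymptotic formula and its identities", {
  # r = 0: the argument collapses exactly and p = 1
  expect_equal(rayleigh(0, 27)$p, 1)
  # p is strictly decreasing in Z at fixed n
  r <- seq(0, 0.9, by = 0.05)
  p <- rayleigh(r, 40)$p
  expect_true(all(diff(p) < 0))
  # Z = n r^2
  expect_equal(rayleigh(0.5, 36)$Z, 9)
})

test_that("uniform phases produce calibrated p-values", {
  set.seed(11)
  for (n in c(20, 50)) {
    ph <- matrix(runif(n * 400, -pi, pi), nrow = n)
    res <- itpc(ph)
    frac <- mean(res$p < 0.05)
    expect_lt(abs(frac - 0.05), 2 * sqrt(0.05 * 0.95 / 400) + 0.01)
  }
})

test_that("significance mask uses a strict threshold", {
  Z <- matrix(c(0, 5, 5.01, 80), 2)
  m <- significance_mask(Z)
  expect_equal(as.vector(m), c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(significance_mask(matrix(0, 3, 3))))
})

test_that("sustained Z normalises per band over the pre-onset cycle", {
  bands <- data.frame(low = c(4, 25), high = c(8, 35))
  fs <- 1000
  nt <- 400; onset <- 300
  Zc <- matrix(7, 2, nt)
  expect_equal(sustained_z(Zc, bands, fs, onset), c(1, 1))
  Zpost <- matrix(0, 2, nt); Zpost[, onset:nt] <- 9
  expect_equal(sustained_z(Zpost, bands, fs, onset), c(0, 0))
})

test_that("sustained Z peaks in a synthetically locked band", {
  g <- deterministic_grammar()
  ann <- sample_behavior(g, 12, seed = 21)
  m <- lfp_model(g$motif,
                 bands = data.frame(low = 25, high = 35, amplitude = 1,
                                    kappa = Inf),
                 channel_count = 2, background_sd = 0.5, seed = 21)
  rec <- synthesize_lfp(ann, m)
  ev <- vocal_events(ann)
  res <- itpc_events(rec, ev$onset[ev$label == "2"],
                     window = c(0.12, 0.05),
                     bands = filterbank_bands(40, c(4, 120)))
  # global-max normalisation: the cross-band comparison (per-frequency
  # normalisation saturates on short epochs, see the methods vignette)
  prof <- sustained_z(res$Z, res$bands, 1000,
                      onset_col = which.min(abs(res$time)),
                      global_max = TRUE)
  best <- res$bands$center[which.max(prof)]
  expect_gt(best, 25 / 1.2)
  expect_lt(best, 35 * 1.2)
})

test_that("perfect phase reset yields ITPC of 1 at the onset sample", {
  g <- deterministic_grammar()
  ann <- sample_behavior(g, 6, seed = 33)
  m <- lfp_model(g$motif,
                 bands = data.frame(low = 25, high = 35, amplitude = 1,
                                    kappa = Inf),
                 channel_count = 1, background_sd = 0, template_snr = 0,
                 seed = 33)
  rec <- synthesize_lfp(ann, m)
  ev <- vocal_events(ann)
  res <- itpc_events(rec, ev$onset[ev$label == "3"],
                     window = c(0.05, 0.05),
                     bands = data.frame(low = 25, high = 35))
  oc <- which.min(abs(res$time))
  expect_equal(res$r[1, oc], 1, tolerance = 1e-6)
})

test_that("null model leaves downstream ITPC p-values uniform", {
  g <- deterministic_grammar()
  ann <- sample_behavior(g, 20, seed = 5)
  m <- lfp_model(g$motif,
                 bands = data.frame(low = 25, high = 35, amplitude = 0,
                                    kappa = 0),
                 highgamma_gain = 1, channel_count = 1, template_snr = 0,
                 seed = 5)
  rec <- synthesize_lfp(ann, m)
  ev <- vocal_events(ann)
  res <- itpc_events(rec, ev$onset[ev$label == "2"],
                     window = c(0.1, 0.1),
                     bands = filterbank_bands(20, c(30, 150)))
  frac <- mean(res$p < 0.05)
  expect_lt(frac, 0.12)
})

test_that("onset phase histograms recover programmed preferred phases", {
  g <- deterministic_grammar()
  ann <- sample_behavior(g, 15, seed = 44)
  pref <- matrix(c(pi / 3, pi / 3 + 1.5, 0, 0, 0), ncol = 1)
  rownames(pref) <- g$motif
  m <- lfp_model(g$motif,
                 bands = data.frame(low = 25, high = 35, amplitude = 1.2,
                                    kappa = Inf),
                 preferred_phase = pref, channel_count = 2,
                 background_sd = 0.2, template_snr = 0, seed = 44)
  rec <- synthesize_lfp(ann, m)
  ev <- vocal_events(ann)
  h1 <- onset_phase_histogram(rec, ev$onset[ev$label == "1"], c(25, 35))
  h2 <- onset_phase_histogram(rec, ev$onset[ev$label == "2"], c(25, 35))
  expect_equal(songlfp:::wrap_angle(h2$mean_direction - h1$mean_direction),
               1.5, tolerance = 0.1)
  expect_equal(h1$mean_direction, pi / 3, tolerance = 0.1)
  expect_equal(sum(h1$counts), h1$n)
})

test_that("alignment contrast is null under zero jitter and positive under jitter", {
  # zero jitter: labeled and stereotyped alignments coincide
  g0 <- deterministic_grammar()
  ann0 <- sample_behavior(g0, 15, seed = 8)
  m0 <- lfp_model(g0$motif, channel_count = 2, seed = 8)
  rec0 <- synthesize_lfp(ann0, m0)
  ann0c <- contextualize(ann0, g0$motif)
  sets0 <- select_and_balance(ann0c, "3", seed = 1)
  ac0 <- alignment_contrast(rec0, sets0[["3"]]$times, sets0[["3"]]$anchors,
                            channels = 1:2)
  expect_equal(max(abs(ac0$difference)), 0, tolerance = 1e-9)
  expect_true(is.na(ac0$p) || ac0$p > 0.05)

  # jittered onsets with onset-locked transients: labeled wins
  g1 <- song_grammar(gap_jitter_ms = 20, branch = c(connector = 0,
                                                    continue = 0, end = 1),
                     intro_count_probs = 1, call_prob = 0)
  ann1 <- sample_behavior(g1, 20, seed = 9)
  m1 <- lfp_model(g1$motif, channel_count = 4, background_sd = 0.4,
                  seed = 9)
  rec1 <- synthesize_lfp(ann1, m1)
  ann1c <- contextualize(ann1, g1$motif)
  sets1 <- select_and_balance(ann1c, "4", seed = 1)
  ac1 <- alignment_contrast(rec1, sets1[["4"]]$times, sets1[["4"]]$anchors,
                            channels = 1:4)
  expect_gt(stats::median(ac1$difference), 0)
  expect_lt(ac1$p, 0.05)
})
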