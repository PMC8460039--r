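# Spectral characterisation: normalisation, z-scores, power tests,
# multitaper, PSC, cosine similarity, d-prime.

test_that("normalized spectrogram has unit band mean over the VAP", {
  rec <- sine_recording(c(30), dur = 6)
  vap <- c(0, 6000)
  st <- normalized_spectrogram(rec, vap, events = c(2000, 3000, 4000),
                               window = c(0.2, 0.2), n_bands = 12,
                               f_range = c(10, 80))
  expect_true(all(st$s >= 0))
  # constant-amplitude band: normalised trace is ~1 in the 30 Hz band
  b30 <- which(st$bands$low <= 30 & st$bands$high >= 30)
  expect_equal(mean(st$s[b30, , 1]), 1, tolerance = 0.05)
})

test_that("doubling amplitude over the second half shifts normalised means", {
  fs <- 1000
  t <- seq_len(6 * fs) / fs
  x <- sin(2 * pi * 30 * t) * rep(c(1, 2), each = 3 * fs)
  rec <- recording(matrix(x, 1), fs)
  flt <- songlfp:::butter_bandpass_sos(4, 25, 35, fs)
  amp <- Mod(analytic_signal(songlfp:::sosfiltfilt(flt, x), fs))
  amp <- amp / mean(amp)
  expect_equal(mean(amp[500:2500]), 2 / 3, tolerance = 0.05)
  expect_equal(mean(amp[3500:5500]), 4 / 3, tolerance = 0.05)
})

test_that("cross-trial z-score matches a literal reimplementation", {
  # hand-computed toy: 2 trials, 1 band, T = 2
  s <- array(c(1, 1, 3, 3), dim = c(1, 2, 2))
  res <- cross_trial_zscore(s)
  expect_equal(as.numeric(res$S), c(0, 0))

  # independent oracle on a 3-trial toy
  set.seed(2)
  s3 <- array(abs(rnorm(2 * 4 * 3)) + 0.5, dim = c(2, 4, 3))
  res3 <- cross_trial_zscore(s3)
  oracle <- array(NA_real_, dim = c(2, 4))
  for (f in 1:2) {
    grand <- mean(s3[f, , ])
    shat <- s3[f, , ] - grand
    for (t in 1:4) {
      oracle[f, t] <- mean(shat[t, ]) / sd(shat[t, ])
    }
  }
  expect_equal(res3$S, oracle, tolerance = 1e-12)

  # identical trials: zero variance everywhere -> flagged zeros
  same <- array(rep(c(1, 2, 3, 4), 3), dim = c(1, 4, 3))
  resd <- cross_trial_zscore(same)
  expect_true(all(resd$flagged))
  expect_true(all(resd$S == 0))
})

test_that("consistent structure scores higher |S| than inconsistent", {
  set.seed(7)
  base <- array(1 + 0.1 * rnorm(1 * 20 * 12), dim = c(1, 20, 12))
  all_tr <- base; all_tr[1, 10, ] <- all_tr[1, 10, ] + 0.5
  half_tr <- base; half_tr[1, 10, 1:6] <- half_tr[1, 10, 1:6] + 1.0
  S_all <- cross_trial_zscore(all_tr)$S[1, 10]
  S_half <- cross_trial_zscore(half_tr)$S[1, 10]
  expect_gt(abs(S_all), abs(S_half))
})

test_that("band power trace is z-scored and detects vocal elevation", {
  set.seed(12)
  rec <- recording(matrix(rnorm(20000), 1), 1000)
  tr <- band_power_trace(rec)
  expect_lt(abs(mean(tr)), 0.05)
  expect_lt(abs(sd(tr) - 1), 0.05)

  s <- small_synth()
  trs <- band_power_trace(s$rec, channel = 1)
  ev <- vocal_events(s$ann)
  voc <- unlist(mapply(function(a, b) (a + 1):b, ev$onset, ev$offset,
                       SIMPLIFY = FALSE))
  voc <- voc[voc <= length(trs)]
  ht <- t.test(trs[voc], trs[-voc], alternative = "greater")
  expect_lt(ht$p.value, 0.01)
})

test_that("power state tests calibrate and detect a 3 SD shift", {
  # identical distributions: p around 0.5, not significant
  set.seed(3)
  pv <- list(list(rnorm(100)))
  ps <- list(list(rnorm(100)))
  r0 <- power_state_tests(pv, ps)
  expect_gt(r0$table$p, 0.05)
  # +3 SD shift at n = 100 is significant after BH
  pv1 <- list(list(rnorm(100, 3), rnorm(100)))
  ps1 <- list(list(rnorm(100), rnorm(100)))
  r1 <- power_state_tests(pv1, ps1)
  expect_true(r1$table$significant[1])
  expect_false(r1$table$significant[2])
  expect_equal(r1$percent_significant, 50)
})

test_that("BH keeps the false discovery rate near its level", {
  set.seed(8)
  n_runs <- 300
  fdp <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    p <- c(runif(20),                        # 20 true nulls
           rbeta(80, 0.05, 1))               # 80 strong effects
    q <- p.adjust(p, "BH")
    rej <- which(q < 0.05)
    fdp[i] <- if (length(rej)) sum(rej <= 20) / length(rej) else 0
  }
  expect_lt(mean(fdp), 0.05 + 2 * sd(fdp) / sqrt(n_runs) + 0.01)
})

test_that("multitaper PSD is flat for white noise and peaks for a tone", {
  set.seed(5)
  fs <- 1000
  x <- rnorm(fs)
  p <- multitaper_psd(x, fs)
  expect_lt(sd(p$psd) / mean(p$psd), 0.3)
  # Parseval: integral of two-sided density ~ variance
  full <- multitaper_psd(x, fs, f_range = c(0, fs / 2))
  tot <- sum(full$psd) * (full$freq[2] - full$freq[1])
  expect_equal(tot, var(x), tolerance = 0.1)

  x2 <- sin(2 * pi * 60 * seq_len(fs) / fs) + 0.2 * rnorm(fs)
  p2 <- multitaper_psd(x2, fs)
  expect_equal(p2$freq[which.max(p2$psd)], 60, tolerance = 2)
})

test_that("dpss tapers are orthonormal and match the concentration ranking", {
  tap <- songlfp:::dpss_tapers(512, 7.5, 14)
  G <- t(tap) %*% tap
  expect_equal(G, diag(14), tolerance = 1e-8)
})

test_that("psc decomposition matches a brute-force eigen oracle", {
  # two-frequency toy with perfectly correlated columns
  Pbar <- matrix(c(1, 1, -1, -1, 1, 1, -1, -1), nrow = 2)
  P <- exp(Pbar)  # psc_decompose recentres; construct directly instead
  C <- Pbar %*% t(Pbar)
  e <- eigen(C, symmetric = TRUE)
  expect_equal(abs(e$vectors[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(e$values[2], 0, tolerance = 1e-12)

  # oracle via the characteristic polynomial on random 3x3 covariance
  set.seed(10)
  M <- matrix(rnorm(12), 3, 4)
  ens <- exp(M)
  res <- psc_decompose(ens)
  Cm <- res$C
  # characteristic polynomial det(C - l I) = -l^3 + a l^2 + b l + c
  a <- sum(diag(Cm))
  b <- -(det(Cm[-1, -1, drop = FALSE]) + det(Cm[-2, -2, drop = FALSE]) +
           det(Cm[-3, -3, drop = FALSE]))
  cc <- det(Cm)
  roots <- sort(Re(polyroot(c(cc, b, a, -1))), decreasing = TRUE)
  expect_equal(res$lambda, roots, tolerance = 1e-8)
  # orthonormality
  expect_equal(t(res$psc) %*% res$psc, diag(3), tolerance = 1e-8)
  # identical trials: everything collapses to zero
  same <- matrix(rep(exp(c(1, 2, 3)), 5), nrow = 3)
  res0 <- psc_decompose(same)
  expect_equal(max(abs(res0$Pbar)), 0, tolerance = 1e-12)
  expect_equal(max(abs(res0$lambda)), 0, tolerance = 1e-12)
})

test_that("PSC sign flips leave projection separation unchanged", {
  set.seed(13)
  P <- exp(matrix(rnorm(40), 4, 10))
  res <- psc_decompose(P)
  d1 <- abs(mean(res$projections[1, 1:5]) - mean(res$projections[1, 6:10]))
  flipped <- -res$psc[, 1]
  proj_f <- as.numeric(t(flipped) %*% res$Pbar)
  d2 <- abs(mean(proj_f[1:5]) - mean(proj_f[6:10]))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("cosine similarity follows its definition", {
  expect_equal(cosine_similarity(c(2, 2), c(1, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero")
  # template construction aligns signs before averaging
  tm <- psc_template(list(c(1, 0), c(-1, 0), c(1, 0)))
  expect_equal(abs(tm), c(1, 0))
})

test_that("d-prime and its permutation null behave", {
  set.seed(14)
  a <- rnorm(100, 2, 1); b <- rnorm(100, 0, 1)
  expect_equal(dprime(a, b), 2, tolerance = 0.2)
  expect_equal(dprime(c(1, 1), c(1, 1)), 0)
  # shuffled labels: significance near alpha
  x <- rnorm(60)
  res <- psc_sensitivity(matrix(x, 1), rep(c("a", "b"), each = 30),
                         n_perm = 500, seed = 3)
  expect_gt(res$p, 0.05)
  # maximal observed statistic gives the permutation bound
  y <- c(rep(0, 30), rep(10, 30)) + rnorm(60, 0, 1e-3)
  res2 <- psc_sensitivity(matrix(y, 1), rep(c("a", "b"), each = 30),
                          n_perm = 500, seed = 3)
  expect_equal(res2$p, 1 / 501, tolerance = 1e-12)
})

test_that("permutation d-prime test is calibrated under the null", {
  set.seed(15)
  hits <- 0; runs <- 120
  for (i in seq_len(runs)) {
    x <- rnorm(40)
    res <- psc_sensitivity(matrix(x, 1), rep(c("a", "b"), 20),
                           n_perm = 200, seed = i)
    if (res$p < 0.05) hits <- hits + 1
  }
  expect_lt(hits / runs, 0.05 + 2 * sqrt(0.05 * 0.95 / runs))
})

test_that("broadband PSC separates vocal from silent trials", {
  s <- small_synth()
  annc <- contextualize(s$ann, s$grammar$motif)
  ev <- vocal_events(annc)
  active <- ev$onset[ev$label == "3"]
  sp <- silent_spans(annc)
  inactive <- round((sp$start + sp$end) / 2)
  ens <- multitaper_trials(s$rec, list(active = active,
                                       inactive = inactive))
  res <- psc_decompose(ens)
  sens <- psc_sensitivity(res$projections[1:3, , drop = FALSE],
                          res$condition, n_perm = 500, seed = 4)
  expect_true(any(sens$significant))
})
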