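test_that("contact selection prefers the channel with the strongest beta peak", {
  freqs <- 1:45
  flat <- rep(1, 45)
  peaked <- flat + 3 * exp(-(freqs - 20)^2 / 8)
  sel <- select_contact(cbind(flat, peaked), freqs)
  expect_equal(sel$channel, 2L)
  expect_equal(sel$peak_hz, 20)
  expect_false(sel$tie)

  # exact tie: lower channel index, flagged
  sel2 <- select_contact(cbind(peaked, peaked), freqs)
  expect_equal(sel2$channel, 1L)
  expect_true(sel2$tie)

  # a 22 Hz peak is located exactly
  p22 <- flat + 2 * exp(-(freqs - 22)^2 / 4)
  expect_equal(select_contact(cbind(flat, p22), freqs)$peak_hz, 22)

  # no local beta peak anywhere: flagged default
  sel3 <- select_contact(cbind(flat, flat + freqs / 100), freqs)
  expect_true(sel3$no_peak)
  expect_equal(sel3$channel, 1L)
})

test_that("preprocessing removes DC, preserves in-band amplitude, rejects low rates", {
  fs_in <- 1000
  t <- seq(0, 10, by = 1 / fs_in)
  x <- 2 + sin(2 * pi * 20 * t)
  out <- preprocess_lfp(x, fs_in)
  expect_equal(out$fs, 200)
  core <- out$values[seq(200, length(out$values) - 200)]
  expect_lt(abs(mean(core)), 0.02)
  # amplitude preserved within 2%
  expect_lt(abs(sqrt(2 * mean(core^2)) - 1), 0.02)
  expect_error(preprocess_lfp(x, 100), "at least")
})

test_that("wavelet power localizes tones and follows the cycle rule", {
  fs <- 200
  t <- seq(0, 20, by = 1 / fs)
  tf <- wavelet_power(sin(2 * pi * 20 * t), fs)
  mid <- tf$valid[, 1] & seq_along(t) > 2 * fs &
    seq_along(t) < length(t) - 2 * fs
  prof <- colMeans(tf$power[mid, ])
  expect_equal(tf$freqs[which.max(prof)], 20)
  # amplitude-preserving normalization: unit sinusoid -> power ~ 1
  expect_lt(abs(mean(tf$power[mid, tf$freqs == 20]) - 1), 0.05)

  # two tones resolved
  tf2 <- wavelet_power(sin(2 * pi * 10 * t) + sin(2 * pi * 25 * t), fs)
  prof2 <- colMeans(tf2$power[mid, ])
  pks <- tf2$freqs[order(prof2, decreasing = TRUE)[1:2]]
  expect_setequal(pks, c(10, 25))

  # AM carrier: 20 Hz power envelope matches the analytic amplitude
  am <- (1 + 0.5 * sin(2 * pi * 0.7 * t)) * sin(2 * pi * 20 * t)
  tf3 <- wavelet_power(am, fs)
  est <- sqrt(tf3$power[mid, tf3$freqs == 20])
  truth <- (1 + 0.5 * sin(2 * pi * 0.7 * t))[mid]
  expect_lt(max(abs(est - truth) / truth), 0.05)

  expect_error(wavelet_power(rnorm(50), fs), "shorter")
})

test_that("per-frequency normalization gives experiment-wide mean one", {
  set.seed(1)
  tf <- wavelet_power(rnorm(4000), 200)
  ntf <- normalize_tf(tf)
  for (j in seq_along(ntf$freqs))
    expect_lt(abs(mean(ntf$power[ntf$valid[, j], j]) - 1), 1e-9)
})

test_that("capped averaging stops at the condition median RT", {
  time_s <- seq(-0.1, 2, by = 0.005)
  traces <- matrix(1, length(time_s), 5)
  rts <- c(0.6, 0.8, 1.0, 1.2, 1.4)
  ca <- capped_average(traces, time_s, rts)
  expect_equal(ca$valid_until_s, 1.0, tolerance = 0.006)
  expect_true(all(is.na(ca$mean[time_s > 1.0])))
  # all RTs beyond the trace: plain mean over the full extent
  ca2 <- capped_average(traces, time_s, rep(5, 5))
  expect_equal(ca2$valid_until_s, max(time_s))
  expect_true(all(ca2$mean == 1))
  # single trial: extent is that trial's RT
  ca3 <- capped_average(traces[, 1, drop = FALSE], time_s, 0.6)
  expect_equal(ca3$valid_until_s, 0.6, tolerance = 0.006)
  expect_error(capped_average(traces[, 0, drop = FALSE], time_s, numeric()),
               "empty")
})

test_that("cue beta decrease recovers an injected drop and z-scores correctly", {
  time_s <- seq(-0.1, 1.5, by = 0.005)
  n <- 60
  set.seed(2)
  drops <- runif(n, 0.2, 0.8)
  traces <- sapply(drops, function(d) {
    y <- rep(1, length(time_s))
    y[time_s >= 0.2 & time_s <= 0.6] <- 1 - d
    y
  })
  raw <- cue_beta_decrease(traces, time_s, zscore = FALSE)
  expect_equal(as.numeric(raw), drops, tolerance = 0.05)
  expect_true(attr(raw, "trough_s") >= 0.3 && attr(raw, "trough_s") <= 0.5)
  z <- cue_beta_decrease(traces, time_s)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # flat traces: zero decrease
  flat <- matrix(1, length(time_s), 4)
  expect_true(all(cue_beta_decrease(flat, time_s, zscore = FALSE) == 0))
  expect_error(cue_beta_decrease(flat[time_s < 0.4, ], time_s[time_s < 0.4]),
               "500 ms")
})

test_that("late beta splits by coherence and honours the exclusion flag", {
  time_s <- seq(-0.1, 1.2, by = 0.005)
  n <- 40
  set.seed(3)
  lev <- runif(n, 0.5, 1.5)
  traces <- sapply(lev, function(a) rep(a, length(time_s)))
  coh <- rep(c("low", "high"), n / 2)
  rts <- runif(n, 0.9, 2)
  lb <- late_beta(traces, time_s, coh, rts)
  expect_equal(lb$beta_late, lev, tolerance = 1e-12)
  low <- coh == "low"
  expect_equal(mean(lb$beta_lc_z[low]), 0, tolerance = 1e-12)
  expect_equal(sd(lb$beta_lc_z[low]), 1, tolerance = 0.01)
  expect_true(all(lb$beta_lc_z[!low] == 0))
  expect_true(all(lb$beta_hc_z[low] == 0))
  # exclusion: a fast trial loses its regressor
  rts2 <- rts; rts2[1] <- 0.7
  lb2 <- late_beta(traces, time_s, coh, rts2, exclude_short = TRUE)
  expect_false(lb2$keep[1])
  expect_equal(lb2$beta_lc_z[1], 0)
  expect_error(late_beta(traces[time_s < 0.7, ], time_s[time_s < 0.7],
                         coh, rts), "late window")
})

test_that("cue decrease and late beta are uncorrelated when the generator couples neither", {
  truth <- default_ground_truth(decrease_coupling = 0, late_coupling = 0)
  coh <- generate_cohort(seed = 77, n_patients = 5, conditions = "off",
                         truth = truth)
  dec <- late <- subj <- c()
  for (p in 1:5) {
    tr <- add_beta_covariates(coh$sessions[[p]]$off)
    i <- tr$coherence == "low" & !tr$omission
    dec <- c(dec, tr$beta_decrease_z[i])
    late <- c(late, tr$beta_late[i])
    subj <- c(subj, rep(p, sum(i)))
  }
  res <- corr_group_test(dec, late, subj)
  expect_lt(max(abs(res$rho)), 0.25)
  expect_gt(res$p, 0.05)
})
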