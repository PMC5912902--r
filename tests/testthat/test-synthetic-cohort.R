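test_that("task schedules satisfy the session design", {
  s <- generate_task(1)
  expect_equal(nrow(s), 240)
  expect_equal(max(s$block_index), 12)
  # instruction constant within 20-trial blocks, alternating between blocks
  per_block <- tapply(s$instruction, s$block_index, unique)
  expect_true(all(lengths(per_block) == 1))
  expect_true(all(per_block[seq(1, 11, 2)] == per_block[[1]]))
  expect_true(all(per_block[seq(2, 12, 2)] != per_block[[1]]))
  expect_equal(sum(table(unlist(per_block))), 12)
  # determinism per seed
  expect_identical(generate_task(1), generate_task(1))
  expect_false(identical(generate_task(1)$coherence, generate_task(2)$coherence))
  # coherence equiprobable within binomial tolerance (n = 240, p = 0.5)
  counts <- sapply(1:20, function(seed) sum(generate_task(seed)$coherence == "low"))
  expect_true(all(abs(counts - 120) <= 4 * sqrt(240 * 0.25)))
  # jitter range and mean
  expect_true(all(s$cue_jitter >= 0.75 & s$cue_jitter <= 1.25))
  jt <- unlist(lapply(1:10, function(seed) generate_task(seed)$cue_jitter))
  expect_lt(abs(mean(jt) - 1), 0.02)
})

test_that("behaviour reproduces the generative effect directions", {
  truth <- default_ground_truth()
  sched <- generate_task(3, n_trials = 6000, block_len = 20)
  beh <- generate_behavior(sched, truth, seed = 4)
  ok <- !beh$omission
  low <- beh$coherence == "low"; sp <- beh$instruction == "speed"
  expect_gt(median(beh$rt_s[ok & low]), median(beh$rt_s[ok & !low]))
  expect_gt(median(beh$rt_s[ok & !sp]), median(beh$rt_s[ok & sp]))
  expect_gt(mean(beh$accuracy[ok & !low]), mean(beh$accuracy[ok & low]))
  expect_lt(mean(beh$omission), 0.03)
  expect_true(all(beh$rt_s[ok] <= truth$deadline_s))
  expect_true(all(is.na(beh$rt_s[!ok])))
})

test_that("a null coherence-threshold effect makes stimulation flags irrelevant", {
  truth <- default_ground_truth(b_coh_a = 0)
  sched <- generate_task(5, n_trials = 4000, block_len = 20)
  b_on <- generate_behavior(sched, truth, rep(TRUE, 4000), seed = 6)
  b_off <- generate_behavior(sched, truth, rep(FALSE, 4000), seed = 6)
  expect_identical(b_on$rt_s, b_off$rt_s)
  expect_identical(b_on$accuracy, b_off$accuracy)
})

test_that("large drift drives accuracy to one; bad truth errors", {
  truth <- default_ground_truth(mu_v = 12, b_coh_v = -2)
  sched <- generate_task(7, n_trials = 1000, block_len = 20)
  beh <- generate_behavior(sched, truth, seed = 8)
  expect_gt(mean(beh$accuracy[!beh$omission]), 0.99)
  expect_error(generate_behavior(sched, default_ground_truth(mu_a = 0.3),
                                 seed = 1),
               "non-positive")
})

test_that("envelope carries the constructed task-locked structure", {
  truth <- default_ground_truth()
  sched <- generate_task(9)
  beh <- generate_behavior(sched, truth, seed = 10)
  env <- generate_lfp(sched, beh, truth, seed = 11)
  fs <- truth$fs
  expect_equal(length(env$cue_samples), 240)
  expect_true(all(diff(env$cue_samples) > 3.5 * fs))

  # trial-wise late bump amplitude couples to the threshold deviation
  low <- beh$coherence == "low"
  expect_gt(cor(env$bump_true[low], beh$eta[low]), 0.5)

  # mean envelope: speed trials drop more steeply over 150-400 ms
  epoch <- function(idx) {
    sapply(env$cue_samples[idx], function(cs)
      env$values[cs:(cs + round(0.45 * fs))])
  }
  rel_drop <- function(idx) {
    m <- rowMeans(epoch(idx))
    mean(m[round(0.38 * fs):round(0.42 * fs)]) / mean(m[1:round(0.1 * fs)])
  }
  expect_lt(rel_drop(beh$instruction == "speed"),
            rel_drop(beh$instruction == "accuracy"))

  # zero coupling: no correlation between late envelope and threshold
  truth0 <- default_ground_truth(late_coupling = 0)
  beh0 <- generate_behavior(sched, truth0, seed = 10)
  env0 <- generate_lfp(sched, beh0, truth0, seed = 11)
  low0 <- which(beh0$coherence == "low" & !beh0$omission &
                  beh0$rt_s > 0.9)
  late0 <- sapply(env0$cue_samples[low0], function(cs)
    mean(env0$values[(cs + round(0.5 * fs)):(cs + round(0.8 * fs))]))
  expect_lt(abs(cor(late0, beh0$eta[low0], method = "spearman")), 0.1)

  # mismatched inputs error
  expect_error(generate_lfp(sched[1:10, ], beh, truth, seed = 1), "mismatch")
})

test_that("session conditions wire stimulation correctly", {
  truth <- default_ground_truth()
  off <- generate_session("off", truth, seed = 12)
  expect_null(off$stim)
  expect_true(all(off$trials$stim == 0))
  cd <- generate_session("cdbs", truth, seed = 12)
  expect_true(all(cd$trials$stim == 1))
  expect_true(all(effective_stim_mask(cd$stim)))
  ad <- generate_session("adbs", truth, seed = 12)
  duty_trig <- mean(ad$stim$trigger_state)
  duty_eff <- mean(effective_stim_mask(ad$stim))
  expect_lt(duty_eff, duty_trig)
  expect_gt(mean(ad$trials$stim), 0.15)
  expect_lt(mean(ad$trials$stim), 0.8)
  expect_error(generate_session("sham"), "arg")
})

test_that("the default cohort has the full design size and round-trips through files", {
  truth <- default_ground_truth(n_trials = 40)   # small for the round-trip
  coh <- generate_cohort(seed = 13, n_patients = 3, truth = truth)
  expect_equal(nrow(coh$trials), 3 * 3 * 40)
  expect_setequal(unique(coh$trials$condition), c("off", "cdbs", "adbs"))
  # every patient sees each condition once, in some order
  tab <- table(coh$trials$patient, coh$trials$condition)
  expect_true(all(tab == 40))

  dir <- tempfile("cohort_")
  write_cohort(coh, dir, include_series = TRUE)
  back <- read_cohort(dir)
  expect_identical(back$trials$rt_s, coh$trials$rt_s)
  expect_identical(back$trials$accuracy, coh$trials$accuracy)
  expect_equal(back$subjects$a_s, coh$subjects$a_s)
  expect_equal(back$truth$mu_a, coh$truth$mu_a)
  s1 <- coh$sessions[[2]]$adbs; s2 <- back$sessions[[2]]$adbs
  expect_identical(s2$envelope$values, s1$envelope$values)
  expect_equal(s2$stim$voltage_fraction, s1$stim$voltage_fraction)
  expect_equal(s2$envelope$cue_samples, s1$envelope$cue_samples)
  unlink(dir, recursive = TRUE)
})

test_that("cohort generation is reproducible from the master seed", {
  t1 <- generate_cohort(seed = 14, n_patients = 2, conditions = "off",
                        truth = default_ground_truth(n_trials = 40))$trials
  t2 <- generate_cohort(seed = 14, n_patients = 2, conditions = "off",
                        truth = default_ground_truth(n_trials = 40))$trials
  expect_identical(t1, t2)
})
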