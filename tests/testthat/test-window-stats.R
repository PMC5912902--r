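test_that("default cue grid has 91 windows with starts 0..900 ms", {
  g <- window_grid("cue")
  expect_equal(length(g$starts_ms), 91)
  expect_equal(g$starts_ms, seq(0, 900, by = 10))
  gr <- window_grid("response")
  expect_equal(length(gr$starts_ms), 91)
  expect_equal(range(gr$starts_ms), c(-1000, -100))
})

test_that("window labels follow half-open interval arithmetic", {
  fs <- 200
  mask <- rep(FALSE, 4000)
  ev <- c(1000L, 2000L)
  g <- window_grid("cue")
  # all-off mask: every label FALSE
  expect_true(all(!window_stim_labels(mask, ev, fs, g)))
  # single effective sample at +450 ms after the first event
  mask2 <- mask
  mask2[1000 + 90] <- TRUE            # +90 samples = +450 ms
  lb <- window_stim_labels(mask2, ev, fs, g)
  hit <- which(lb[1, ])
  # windows [start, start+100) containing 450 ms: starts 360..450 ms
  expect_equal(g$starts_ms[hit], seq(360, 450, by = 10))
  expect_true(all(!lb[2, ]))
  # all-on mask: every label TRUE
  expect_true(all(window_stim_labels(!mask, ev, fs, g)))
  # event too close to the edge errors
  expect_error(window_stim_labels(mask, c(3950L), fs, g), "extent")
})

test_that("percent time on averages the mask per window", {
  fs <- 200
  g <- window_grid("cue")
  ev <- c(500L, 1500L)
  expect_equal(percent_time_on(rep(TRUE, 3000), ev, fs, g), rep(100, 91))
  # ON exactly half of every window: alternate 10-sample blocks
  mask <- rep(rep(c(TRUE, FALSE), each = 10), length.out = 3000)
  pct <- percent_time_on(mask, ev, fs, g)
  expect_true(all(abs(pct - 50) <= 5))
  # smoothness: 10 ms steps on a 100 ms window change at most 10% of it
  set.seed(1)
  mask2 <- runif(3000) < 0.3
  pct2 <- percent_time_on(mask2, ev, fs, g)
  expect_lte(max(abs(diff(pct2))), 10)
})

test_that("stim_contrast recovers injected effects and degenerates loudly", {
  set.seed(2)
  n <- 400
  trials <- tibble::tibble(
    patient = rep(1:4, each = n),
    coherence = sample(c("low", "high"), 4 * n, replace = TRUE),
    rt_s = 0.8 + 0.5 * (rep(1, 4 * n)) * 0,
    omission = FALSE
  )
  trials$rt_s <- 0.8 + 0.4 * (trials$coherence == "low") +
    rnorm(4 * n, 0, 0.05)
  labels <- matrix(sample(c(TRUE, FALSE), 4 * n * 5, replace = TRUE), ncol = 5)
  # identical distributions in stim and no-stim cells: contrast ~ 0
  eff <- stim_contrast(trials, labels, "coherence")
  expect_lt(max(abs(eff)), 30)
  # injected reduction of slowing in stimulated trials, window 3 only
  trials2 <- trials
  hit <- labels[, 3] & trials2$coherence == "low"
  trials2$rt_s[hit] <- trials2$rt_s[hit] - 0.3
  eff2 <- stim_contrast(trials2, labels, "coherence")
  expect_true(all(eff2[, 3] < -250))
  # other windows see the shifted trials in both cells: contrast bounded
  # by mixture-median noise, far from the injected window
  expect_lt(max(abs(eff2[, -3])), 200)
  # continuous stimulation leaves no no-stim cell: explicit error, not 0
  expect_error(stim_contrast(trials, matrix(TRUE, 4 * n, 5), "coherence"),
               "no window")
})

test_that("cluster permutation finds injected clusters and respects ordering invariance", {
  set.seed(3)
  effects <- matrix(rnorm(7 * 91, 0, 30), 7, 91)
  effects[, 40:50] <- effects[, 40:50] - 300
  cl <- cluster_permutation(effects, n_perm = 500, seed = 1)
  expect_gte(nrow(cl), 1)
  top <- cl[which.max(cl$mass), ]
  expect_true(top$significant)
  expect_lte(top$start, 42)
  expect_gte(top$end, 48)
  expect_true(all(cl$p_value > 0 & cl$p_value <= 1))

  # all-zero effects: no clusters
  cl0 <- cluster_permutation(matrix(0, 7, 91), n_perm = 100, seed = 1)
  expect_equal(nrow(cl0), 0)

  # p-values invariant to reordering windows within the cluster
  effects2 <- effects
  effects2[, 44:46] <- effects[, c(46, 45, 44)]
  cl2 <- cluster_permutation(effects2, n_perm = 500, seed = 1)
  expect_equal(max(cl2$mass), max(cl$mass), tolerance = 1e-12)
  expect_equal(cl2$p_value[which.max(cl2$mass)],
               cl$p_value[which.max(cl$mass)])
  expect_error(cluster_permutation(effects[1, , drop = FALSE]), "patients")
})

test_that("windows with too few contributing patients are excluded", {
  set.seed(4)
  effects <- matrix(rnorm(6 * 20, 0, 1), 6, 20)
  effects[1:4, 5] <- NA              # only 2 patients left in window 5
  effects[, 10] <- 100               # would be a huge cluster
  effects[3:6, 10] <- NA             # but only 2 patients contribute
  cl <- cluster_permutation(effects, n_perm = 100, seed = 2,
                            min_patients = 4)
  z <- attr(cl, "z")
  expect_equal(z[5], 0)
  expect_equal(z[10], 0)
})

test_that("the injected 400-500 ms stimulation effect is detected across seeded cohorts", {
  hits <- vapply(1:10, function(s) {
    coh <- generate_cohort(400 + s, conditions = "adbs")
    lab <- cohort_window_labels(coh)
    eff <- stim_contrast(lab$cue$trials, lab$cue$labels, "coherence")
    cl <- cluster_permutation(eff, n_perm = 200, seed = 400 + s)
    g <- window_grid("cue")
    sig <- cl[cl$significant, , drop = FALSE]
    # a significant cluster must cover the causal window region, with
    # negative contrasts (reduced difficulty-related slowing)
    any(vapply(seq_len(nrow(sig)), function(j) {
      w <- sig$start[j]:sig$end[j]
      any(g$starts_ms[w] >= 300 & g$starts_ms[w] <= 500) &&
        mean(attr(cl, "z")[w]) < 0
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
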