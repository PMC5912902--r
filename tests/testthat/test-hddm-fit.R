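# small shared cohort for model-construction tests (no MCMC needed)
make_trials <- function(n = 200, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    patient = rep(1:2, each = n / 2),
    instruction = sample(c("speed", "accuracy"), n, replace = TRUE),
    coherence = sample(c("low", "high"), n, replace = TRUE),
    stim = sample(0:1, n, replace = TRUE),
    rt_s = runif(n, 0.4, 2),
    accuracy = sample(0:1, n, replace = TRUE, prob = c(0.2, 0.8)),
    omission = FALSE
  )
}

test_that("model variants build the documented designs", {
  tr <- make_trials()
  m1 <- build_model(tr, "M1")
  expect_equal(m1$coef_names, c("a_Instr", "a_Coh", "v_Coh"))
  m2 <- build_model(tr, "M2")
  expect_equal(length(m2$coef_names), 9)
  expect_equal(unname(m2$b_labels), paste0("b", 1:9))
  m3 <- build_model(tr, "M3")
  expect_true(all(c("a_Coh_Stim", "a_Coh_noStim") %in% m3$coef_names))
  # split regressors partition the coherence indicator
  expect_equal(m3$Xa[, "Coh_Stim"] + m3$Xa[, "Coh_noStim"],
               as.numeric(m3$trials$coherence == "low"))
  # missing column errors
  expect_error(build_model(tr[, setdiff(names(tr), "stim")], "M2"),
               "stim")
  expect_error(build_model(tr, "M6"), "beta_lc_z")
  # omissions and fast RTs are excluded
  tr2 <- tr
  tr2$rt_s[1:10] <- 0.1
  tr2$omission[11:20] <- TRUE
  expect_equal(length(build_model(tr2, "M1")$rt), nrow(tr) - 20)
})

test_that("posterior probabilities follow the draws", {
  expect_equal(posterior_probability(rep(1, 2000)), 1)
  expect_equal(posterior_probability(rep(-1, 2000), "<"), 1)
  set.seed(1)
  sym <- rnorm(20000)
  expect_lt(abs(posterior_probability(sym) - 0.5), 0.02)
  # draw-wise comparison of two posteriors
  expect_equal(posterior_probability(rnorm(2000) + 10, ref = rnorm(2000)), 1)
  expect_error(posterior_probability(numeric()), "empty")
  expect_warning(posterior_probability(rnorm(10)), "1000")
})

test_that("rhat is ~1 for identical chains and large for disjoint chains", {
  set.seed(2)
  x <- rnorm(500)
  expect_lt(abs(rhat(cbind(x, x + 1e-9)) - 1), 0.01)
  expect_gt(rhat(cbind(rnorm(500), rnorm(500) + 50)), 10)
  expect_error(rhat(matrix(x, ncol = 1)), "chains")
})

test_that("a hierarchical fit recovers single-subject parameters and is seed-deterministic", {
  truth_p <- ddm_params(v = 2, a = 1.6, t = 0.3)
  sim <- simulate_ddm(truth_p, 3000, dt = 1e-4, seed = 3)
  tr <- tibble::tibble(
    patient = 1L,
    instruction = "accuracy", coherence = "high", stim = 0L,
    rt_s = sim$rt, accuracy = as.integer(sim$boundary == "upper"),
    omission = is.na(sim$rt)
  )
  m <- build_model(tr, ddm_spec("custom"))
  fit <- fit_ddm(m, n_draws = 600, n_burn = 800, thin = 2, seed = 4)
  est <- apply(fit$draws, 3, mean)[c("a[1]", "v[1]", "t[1]")]
  expect_lt(abs(est[1] - 1.6) / 1.6, 0.05)
  expect_lt(abs(est[2] - 2) / 2, 0.05)
  expect_lt(abs(est[3] - 0.3) / 0.3, 0.05)
  expect_true(all(fit$rhat[c("a[1]", "v[1]", "t[1]")] < 1.1))

  # identical refit: identical draws, deviance, and DIC
  fit2 <- fit_ddm(m, n_draws = 600, n_burn = 800, thin = 2, seed = 4)
  expect_identical(fit$draws, fit2$draws)
  expect_identical(fit$dic$dic, fit2$dic$dic)
  # DIC parts are coherent: pD > 0, dic = d_hat + 2 pD
  expect_gt(fit$dic$p_d, 0)
  expect_equal(fit$dic$dic, fit$dic$d_hat + 2 * fit$dic$p_d)
})

test_that("quantile-probability coordinates multiply percentile by response probability", {
  set.seed(5)
  n <- 500
  obs <- tibble::tibble(
    instruction = "accuracy",
    coherence = rep(c("low", "high"), each = n),
    rt_s = c(rlnorm(n, -0.2, 0.3), rlnorm(n, -0.7, 0.25)),
    accuracy = c(rbinom(n, 1, 0.8), rbinom(n, 1, 0.995))
  )
  qp <- qp_summary(obs, min_errors = 5)
  low_corr <- qp[qp$condition == "accuracy/low" & qp$response == "correct", ]
  acc_low <- mean(obs$accuracy[obs$coherence == "low"])
  expect_equal(low_corr$cum_prob, c(10, 30, 50, 70, 90) / 100 * acc_low)
  # error quantiles present for low (many errors), absent for high (<5)
  expect_true(any(qp$condition == "accuracy/low" & qp$response == "error"))
  expect_false(any(qp$condition == "accuracy/high" & qp$response == "error"))
  # perfect prediction: predictive equals observed
  qp2 <- qp_summary(obs, predicted = list(obs, obs))
  expect_equal(qp2$rt_pred_mean, qp2$rt_q, tolerance = 1e-12)
  expect_true(all(qp2$rt_pred_sd == 0))
  expect_error(qp_summary(obs[0, ]), "empty")
})

test_that("posterior predictive quantiles cover the observed quantile-probability points", {
  truth <- default_ground_truth(n_trials = 120)
  coh <- generate_cohort(seed = 31, n_patients = 3, conditions = "off",
                         truth = truth, keep_sessions = FALSE)
  fit <- fit_ddm(build_model(coh$trials, "M1"), n_draws = 600, n_burn = 800,
                 thin = 2, seed = 6)
  pred <- posterior_predict(fit, n_rep = 40, seed = 7)
  qp <- qp_summary(fit$model$trials, pred, min_errors = 8)
  corr <- qp[qp$response == "correct", ]
  dev <- abs(corr$rt_q - corr$rt_pred_mean) / pmax(corr$rt_pred_sd, 1e-6)
  # observed points lie within ~2 predictive SD of the predictive mean
  expect_gte(mean(dev <= 2), 0.8)
  expect_lt(max(abs(corr$cum_prob - corr$cum_prob_pred)), 0.1)
})

test_that("DIC favours the model matching the generative stimulation split", {
  coh <- generate_cohort(seed = 91, conditions = "adbs",
                         keep_sessions = FALSE)
  ad <- coh$trials
  fit_split <- fit_ddm(build_model(ad, "M3"), n_draws = 600, n_burn = 800,
                       thin = 2, seed = 8)
  fit_plain <- fit_ddm(build_model(ad, "M1"), n_draws = 600, n_burn = 800,
                       thin = 2, seed = 8)
  # the generator removes the coherence-threshold increment only in
  # stimulated trials; the split model should earn its extra parameters
  expect_lt(fit_split$dic$dic, fit_plain$dic$dic)
})
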