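#' Generator ground truth
#'
#' Parameter set defining the synthetic study conditions: group-level DDM
#' parameters, the generative effect coefficients (instruction and
#' coherence on threshold, coherence on drift), the stimulation effect
#' (removal of the coherence-threshold increment in trials with effective
#' stimulation 400-500 ms post-cue), and the beta-envelope model (bursty
#' mean-reverting baseline, cue-locked decrease, late relative increase in
#' low-coherence trials coupled to the trial's generative threshold, and a
#' response-locked decrease).
#'
#' Defaults are calibrated so an off-stimulation cohort reproduces the
#' approximate magnitudes of the reference behaviour: median RT slowing of
#' roughly 0.68 s in low- vs high-coherence trials, roughly 0.15 s speeding
#' after speed instructions, accuracy near 78% (low) and 98% (high)
#' coherence, and omissions below 2% at the 3 s deadline.
#'
#' @param ... named overrides of any default element.
#' @return A list of class `ddm_ground_truth`.
#' @export
default_ground_truth <- function(...) {
  truth <- list(
    # group-level DDM parameters (evidence units, s = 1 convention)
    mu_a = 1.5, mu_v = 3.2, mu_t = 0.35,
    sig_a = 0.12, sig_v = 0.3, sig_t = 0.04,
    # generative effect coefficients
    b_instr_a = -0.6,    # speed instruction lowers the threshold
    b_coh_a   = 0.8,     # low coherence raises the threshold
    b_coh_v   = -2.5,    # low coherence lowers the drift rate
    trial_sd_a = 0.15,   # trial-wise threshold variability (eta)
    stim_effect = 1,     # fraction of b_coh_a removed when stimulated
    stim_window = c(0.4, 0.5),  # seconds post-cue defining "stimulated"
    # behaviour simulation
    deadline_s = 3, rt_min_s = 0.25, sim_dt = 2e-4,
    # beta-envelope model
    fs = 200,
    ar_tau_s = 0.4,      # correlation time of the log-amplitude baseline
    ln_sd = 0.3,         # log-amplitude SD (burst-like episodes)
    amp0 = 1,
    cue_drop = c(accuracy = 0.25, speed = 0.40),
    drop_window = c(0.15, 0.40),
    drop_noise = 0.05,
    decrease_coupling = 0.3,  # higher-threshold trials drop less
    late_window = c(0.5, 0.8),
    late_base = 0.85,         # fixed post-trough recovery level of the gain
    late_gain = 0.15,
    late_coupling = 0.8,      # gain per unit threshold deviation (eta)
    late_noise = 0.05,
    high_extra_drop = 0.15,   # high coherence keeps decreasing post 500 ms
    resp_drop = 0.3,
    resp_delay = 0.2,         # dip onset after the keypress
    carrier_hz = 21, carrier_noise = 0.15,
    smooth_ms = 400,          # controller-side envelope smoothing
    ramp_ms = 250, lockout_ms = 500,
    # task schedule
    n_trials = 240, block_len = 20, jitter_range = c(0.75, 1.25)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(truth))
  if (length(bad)) stop("unknown ground-truth fields: ", paste(bad, collapse = ", "))
  truth[names(over)] <- over
  if (truth$mu_a <= 0) stop("group threshold mean must be positive")
  structure(truth, class = "ddm_ground_truth")
}

#' Draw subject-level parameters from the group distributions
#'
#' @param truth a [default_ground_truth()] object.
#' @param n_patients number of subjects.
#' @param seed optional integer seed.
#' @return Tibble with one row per subject (`a_s`, `v_s`, `t_s`).
#' @export
draw_subjects <- function(truth, n_patients = 7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw_pos <- function(n, m, s, lo) {
    x <- stats::rnorm(n, m, s)
    while (any(x <= lo)) x[x <= lo] <- stats::rnorm(sum(x <= lo), m, s)
    x
  }
  tibble::tibble(
    patient = seq_len(n_patients),
    a_s = draw_pos(n_patients, truth$mu_a, truth$sig_a, 0.3),
    v_s = stats::rnorm(n_patients, truth$mu_v, truth$sig_v),
    t_s = draw_pos(n_patients, truth$mu_t, truth$sig_t, 0.05)
  )
}

#' Generate one session's task schedule
#'
#' 240 trials in 12 alternating 20-trial instruction blocks (6 blocks per
#' instruction, starting instruction randomized), equiprobable and
#' unpredictable coherence, and a pre-cue jitter uniform on
#' \[0.75, 1.25\] s (mean 1 s).
#'
#' @param seed integer seed; the schedule is deterministic per seed.
#' @param n_trials trials per session (default 240).
#' @param block_len trials per instruction block (default 20).
#' @param jitter_range pre-cue jitter range in seconds.
#' @return Tibble with `trial_index`, `block_index`, `instruction`,
#'   `coherence`, `cue_jitter`.
#' @export
generate_task <- function(seed, n_trials = 240, block_len = 20,
                          jitter_range = c(0.75, 1.25)) {
  stopifnot(n_trials %% block_len == 0)
  set.seed(seed)
  n_blocks <- n_trials / block_len
  first <- sample(c("speed", "accuracy"), 1)
  other <- setdiff(c("speed", "accuracy"), first)
  instr_block <- rep(c(first, other), length.out = n_blocks)
  tibble::tibble(
    trial_index = seq_len(n_trials),
    block_index = rep(seq_len(n_blocks), each = block_len),
    instruction = rep(instr_block, each = block_len),
    coherence = sample(c("low", "high"), n_trials, replace = TRUE),
    cue_jitter = stats::runif(n_trials, jitter_range[1], jitter_range[2])
  )
}

#' Generate behaviour for one session from the DDM
#'
#' Samples RT and choice for every scheduled trial from the generating
#' drift-diffusion process.  Per-trial thresholds are
#' `a_s + b_instr_a * Instr + b_coh_a * Coh + eta` with trial noise `eta`;
#' in trials flagged as stimulated 400-500 ms post-cue the
#' coherence-threshold increment is removed (scaled by `stim_effect`).
#' Responses later than the 3 s deadline are marked as omissions.
#'
#' @param schedule a [generate_task()] tibble.
#' @param truth a [default_ground_truth()] object.
#' @param stim_flags optional logical vector (per trial): effectively
#'   stimulated in the 400-500 ms window.
#' @param seed integer seed.
#' @param subject optional list/row with subject-level `a_s`, `v_s`, `t_s`
#'   (defaults to the group means).
#' @return Tibble with the schedule columns plus `rt_s`, `accuracy`,
#'   `omission`, `stim`, and the generative truth columns `a_true`,
#'   `v_true`, `eta`.
#' @export
generate_behavior <- function(schedule, truth, stim_flags = NULL, seed = NULL,
                              subject = NULL) {
  n <- nrow(schedule)
  if (is.null(subject))
    subject <- list(a_s = truth$mu_a, v_s = truth$mu_v, t_s = truth$mu_t)
  if (is.null(stim_flags)) stim_flags <- rep(FALSE, n)
  if (length(stim_flags) != n) stop("schedule/stim_flags length mismatch")
  if (!is.null(seed)) set.seed(seed)

  low <- schedule$coherence == "low"
  speed <- schedule$instruction == "speed"
  coh_inc <- truth$b_coh_a * low
  coh_inc[stim_flags & low] <- coh_inc[stim_flags & low] * (1 - truth$stim_effect)
  det <- subject$a_s + truth$b_instr_a * speed + coh_inc
  if (any(det <= 0.05))
    stop("ground truth yields non-positive trial thresholds")
  # trial noise truncated so thresholds stay positive (tail draws beyond
  # the deterministic part minus a 0.05 floor are redrawn)
  eta <- stats::rnorm(n, 0, truth$trial_sd_a)
  bad <- which(det + eta <= 0.05)
  while (length(bad)) {
    eta[bad] <- stats::rnorm(length(bad), 0, truth$trial_sd_a)
    bad <- bad[det[bad] + eta[bad] <= 0.05]
  }
  a_k <- det + eta
  v_k <- subject$v_s + truth$b_coh_v * low
  t_k <- rep(subject$t_s, n)

  sim <- ddm_simulate_cpp(a_k, v_k, t_k, 0.5, truth$sim_dt, 20)
  rt <- sim$rt
  omission <- is.na(rt) | rt > truth$deadline_s
  acc <- as.integer(sim$upper)
  rt[omission] <- NA_real_
  acc[omission] <- NA_integer_

  out <- schedule
  out$rt_s <- rt
  out$accuracy <- acc
  out$omission <- omission
  out$stim <- as.integer(stim_flags)
  out$a_true <- a_k
  out$v_true <- v_k
  out$eta <- eta
  out
}

# session timeline: fixed-length trial slots (jitter + deadline + feedback)
# so cue times do not depend on realized RTs; this keeps the closed-loop
# feedback pass exactly consistent with the stimulation-free pass
session_timeline <- function(behavior, truth, pre_roll = 2) {
  slot <- truth$deadline_s + 0.5
  cue <- pre_roll + cumsum(behavior$cue_jitter) +
    slot * (seq_len(nrow(behavior)) - 1)
  list(cue_s = cue, resp_s = ifelse(behavior$omission, NA, cue + behavior$rt_s),
       total_s = cue[length(cue)] + truth$deadline_s + 2)
}

#' Generate the beta-amplitude envelope (and carrier LFP) for a session
#'
#' The envelope is a burst-like mean-reverting baseline (exponentiated
#' Ornstein-Uhlenbeck log-amplitude, correlation time `ar_tau_s`)
#' modulated by a deterministic per-trial gain profile: a cue-locked
#' decrease over 150-400 ms (steeper after speed instructions and, via
#' `decrease_coupling`, shallower in high-threshold trials), a relative
#' increase 500-800 ms post-cue in low-coherence trials whose amplitude is
#' linearly coupled to the trial's generative threshold deviation
#' (`late_coupling`), a continued decrease in high-coherence trials, and a
#' response-locked decrease.  A sinusoidal carrier at the subject's beta
#' peak frequency plus white noise is returned alongside as a synthetic
#' raw LFP for the time-frequency chain.
#'
#' @inheritParams generate_behavior
#' @param behavior a [generate_behavior()] tibble for the same schedule.
#' @return A [beta_envelope()] with event markers and extra fields `lfp`
#'   (carrier + noise), `drop_true`, `bump_true` (per-trial gain truth).
#' @export
generate_lfp <- function(schedule, behavior, truth, seed = NULL) {
  if (nrow(schedule) != nrow(behavior))
    stop("schedule/behavior length mismatch")
  if (!is.null(seed)) set.seed(seed)
  fs <- truth$fs
  tl <- session_timeline(behavior, truth)
  n <- ceiling(tl$total_s * fs)

  # baseline: exponentiated OU log-amplitude, stationary unit-variance
  rho <- exp(-1 / (fs * truth$ar_tau_s))
  warm <- ceiling(5 * truth$ar_tau_s * fs)
  innov <- stats::rnorm(n + warm, 0, sqrt(1 - rho^2))
  x <- as.numeric(stats::filter(innov, rho, method = "recursive"))[-seq_len(warm)]
  amp <- truth$amp0 * exp(truth$ln_sd * x)

  cue_smp <- round(tl$cue_s * fs) + 1L
  resp_smp <- ifelse(is.na(tl$resp_s), NA_integer_, round(tl$resp_s * fs) + 1L)

  n_tr <- nrow(behavior)
  speed <- behavior$instruction == "speed"
  low <- behavior$coherence == "low"
  eta <- behavior$eta
  drop_k <- truth$cue_drop[ifelse(speed, "speed", "accuracy")] -
    truth$decrease_coupling * eta + stats::rnorm(n_tr, 0, truth$drop_noise)
  drop_k <- pmin(pmax(drop_k, 0.02), 0.8)
  bump_k <- truth$late_gain + truth$late_coupling * eta +
    stats::rnorm(n_tr, 0, truth$late_noise)
  bump_k <- pmax(bump_k, 0)

  gain <- rep(1, n)
  seg <- function(from_s, to_s, cs) {   # sample index range rel. to cue
    i0 <- cs + round(from_s * fs); i1 <- cs + round(to_s * fs) - 1L
    if (i1 < i0) integer() else i0:i1
  }
  dw <- truth$drop_window; lw <- truth$late_window
  r0 <- truth$late_base
  for (k in seq_len(n_tr)) {
    cs <- cue_smp[k]
    g_floor <- 1 - drop_k[k]
    # cue-locked decrease to the trial's trough
    i <- seg(dw[1], dw[2], cs)
    gain[i] <- seq(1, g_floor, length.out = length(i))
    if (low[k]) {
      # post-trough rebound to a fixed recovery level, then the relative
      # increase 500-800 ms whose amplitude tracks the trial threshold
      i <- seg(dw[2], lw[1], cs)
      gain[i] <- seq(g_floor, r0, length.out = length(i))
      i <- seg(lw[1], lw[1] + 0.15, cs)
      gain[i] <- seq(r0, r0 + bump_k[k], length.out = length(i))
      i <- seg(lw[1] + 0.15, lw[2], cs)
      gain[i] <- r0 + bump_k[k]
      i <- seg(lw[2], lw[2] + 0.2, cs)
      gain[i] <- seq(r0 + bump_k[k], r0, length.out = length(i))
      i <- seg(lw[2] + 0.2, 1.5, cs)
      gain[i] <- r0
    } else {
      # easy trials keep decreasing (responses come early)
      i <- seg(dw[2], 1.5, cs)
      gain[i] <- pmax(g_floor - truth$high_extra_drop,
                      seq(g_floor, g_floor - truth$high_extra_drop,
                          length.out = length(i)))
    }
    # brief motor-execution beta decrease: dip follows the keypress
    # after resp_delay (ramp 100 ms, hold 100 ms, recover 250 ms).  It is
    # modelled only when its onset clears the late analysis window, so
    # in-window beta carries no response-time structure by construction:
    # the generator's null (zero coupling) is exact, which the recovery
    # tests require (the confound on real data is a documented limitation)
    dip_ok <- !is.na(resp_smp[k]) &&
      resp_smp[k] + round(truth$resp_delay * fs) >=
        cs + round((lw[2] + 0.1) * fs)
    if (dip_ok) {
      rs <- resp_smp[k] + round(truth$resp_delay * fs)
      i <- rs:(rs + round(0.1 * fs))
      i <- i[i >= 1 & i <= n]
      dip <- seq(1, 1 - truth$resp_drop, length.out = length(i))
      gain[i] <- gain[i] * dip
      j <- (rs + round(0.1 * fs) + 1L):(rs + round(0.2 * fs))
      j <- j[j >= 1 & j <= n]
      gain[j] <- gain[j] * (1 - truth$resp_drop)
      j <- (rs + round(0.2 * fs) + 1L):(rs + round(0.45 * fs))
      j <- j[j >= 1 & j <= n]
      gain[j] <- gain[j] * seq(1 - truth$resp_drop, 1, length.out = length(j))
    }
  }

  env_values <- amp * gain
  tt <- seq_len(n) / fs
  lfp <- env_values * sin(2 * pi * truth$carrier_hz * tt +
                          stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n, 0, truth$carrier_noise)

  env <- new_beta_envelope(env_values, fs, cue_smp, resp_smp)
  env$lfp <- lfp
  env$drop_true <- drop_k
  env$bump_true <- bump_k
  env
}

#' Generate one complete session (behaviour, envelope, stimulation)
#'
#' For `"adbs"` the closed-loop controller is run on the smoothed envelope
#' (threshold at its median) and the resulting effective-stimulation flags
#' feed back into the behaviour: the envelope up to 500 ms post-cue does
#' not depend on the behavioural outcome, so flags from a provisional
#' stimulation-free pass carry over exactly to the final pass, which
#' regenerates behaviour and envelope with the same noise streams.  For
#' `"cdbs"` the effective mask is all-ON (every trial stimulated); for
#' `"off"` all-OFF.
#'
#' @param condition one of `"off"`, `"cdbs"`, `"adbs"`.
#' @param truth a [default_ground_truth()].
#' @param subject subject-level parameters (see [generate_behavior()]).
#' @param seed integer seed.
#' @return List of class `adbs_session`: `trials`, `envelope`,
#'   `stim` (a `stim_trace` or NULL for off), `condition`, `threshold`.
#' @export
generate_session <- function(condition = c("off", "cdbs", "adbs"),
                             truth = default_ground_truth(),
                             subject = NULL, seed = 1) {
  condition <- match.arg(condition)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 4)
  schedule <- generate_task(seeds[1], truth$n_trials, truth$block_len,
                            truth$jitter_range)

  if (condition == "off" || condition == "cdbs") {
    flags <- rep(condition == "cdbs", truth$n_trials)
    trials <- generate_behavior(schedule, truth, flags, seeds[2], subject)
    env <- generate_lfp(schedule, trials, truth, seeds[3])
    stim <- NULL
    threshold <- NA_real_
    if (condition == "cdbs") {
      nn <- length(env$values)
      stim <- new_stim_trace(truth$fs, rep(1L, nn), rep(1, nn))
    }
  } else {
    # pass 1: stimulation-free behaviour fixes the trial noise; the
    # controller then determines which trials are hit 400-500 ms post-cue
    prov <- generate_behavior(schedule, truth, NULL, seeds[2], subject)
    prov_env <- generate_lfp(schedule, prov, truth, seeds[3])
    sm <- smooth_causal(prov_env$values, truth$fs, truth$smooth_ms)
    threshold <- stats::median(sm)
    prov_stim <- run_trigger(sm, threshold, truth$ramp_ms, truth$lockout_ms,
                             fs = truth$fs)
    flags <- stim_flags_from_mask(effective_stim_mask(prov_stim),
                                  prov_env$cue_samples, truth$fs,
                                  truth$stim_window)
    # pass 2: same noise streams, now with the stimulation effect injected
    trials <- generate_behavior(schedule, truth, flags, seeds[2], subject)
    env <- generate_lfp(schedule, trials, truth, seeds[3])
    sm <- smooth_causal(env$values, truth$fs, truth$smooth_ms)
    stim <- run_trigger(sm, threshold, truth$ramp_ms, truth$lockout_ms,
                        fs = truth$fs)
  }
  structure(list(trials = trials, envelope = env, stim = stim,
                 condition = condition, threshold = threshold),
            class = "adbs_session")
}

# was there any effective stimulation inside [win[1], win[2]) s post-cue?
stim_flags_from_mask <- function(mask, cue_samples, fs, win = c(0.4, 0.5)) {
  i0 <- cue_samples + round(win[1] * fs)
  i1 <- cue_samples + round(win[2] * fs) - 1L
  vapply(seq_along(cue_samples), function(k) {
    lo <- max(1L, i0[k]); hi <- min(length(mask), i1[k])
    if (hi < lo) return(FALSE)
    any(mask[lo:hi])
  }, logical(1))
}

#' Generate the full synthetic cohort
#'
#' Default study conditions: 7 patients x 3 sessions (off, continuous,
#' adaptive stimulation) x 240 trials = 5,040 trials, with subject-level
#' parameters drawn from the group distributions, session order
#' randomized per patient, and all ground truth recorded alongside.
#'
#' @param seed master seed; per-session substreams are derived from it
#'   deterministically.
#' @param n_patients number of patients (default 7).
#' @param conditions session conditions (default off/cdbs/adbs).
#' @param truth a [default_ground_truth()].
#' @param keep_sessions keep envelopes and stimulation traces (default
#'   TRUE; set FALSE to save memory when only behaviour is needed).
#' @return List of class `adbs_cohort`: `trials` (one combined tibble with
#'   `patient`, `session`, `condition` columns), `sessions` (nested list),
#'   `subjects`, `truth`, `seed`.
#' @export
generate_cohort <- function(seed = 1, n_patients = 7,
                            conditions = c("off", "cdbs", "adbs"),
                            truth = default_ground_truth(),
                            keep_sessions = TRUE) {
  set.seed(seed)
  subjects <- draw_subjects(truth, n_patients)
  sess_seeds <- matrix(sample.int(.Machine$integer.max,
                                  n_patients * length(conditions)),
                       nrow = n_patients)
  orders <- matrix(0L, n_patients, length(conditions))
  for (i in seq_len(n_patients))
    orders[i, ] <- sample.int(length(conditions))

  all_trials <- vector("list", n_patients * length(conditions))
  sessions <- if (keep_sessions) vector("list", n_patients) else NULL
  idx <- 0L
  for (p in seq_len(n_patients)) {
    if (keep_sessions) sessions[[p]] <- list()
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      ses <- generate_session(cond, truth, subjects[p, ], sess_seeds[p, ci])
      idx <- idx + 1L
      tr <- ses$trials
      tr$patient <- p
      tr$session <- which(orders[p, ] == ci)   # chronological position
      tr$condition <- cond
      all_trials[[idx]] <- tr
      if (keep_sessions) sessions[[p]][[cond]] <- ses
    }
  }
  trials <- do.call(rbind, all_trials)
  cols <- c("patient", "session", "condition", "block_index", "instruction",
            "coherence", "cue_jitter", "rt_s", "accuracy", "omission",
            "stim", "trial_index", "a_true", "v_true", "eta")
  trials <- trials[, cols]
  structure(list(trials = trials, sessions = sessions, subjects = subjects,
                 truth = truth, seed = seed),
            class = "adbs_cohort")
}

#' @export
print.adbs_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(unique(x$trials$patient)), "patients,",
      nrow(x$trials), "trials, conditions:",
      paste(unique(x$trials$condition), collapse = "/"), "\n")
  invisible(x)
}
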