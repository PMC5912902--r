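#' Pipeline run configuration
#'
#' Fully serializable description of an end-to-end run; a run is
#' reproducible from its config plus the master seed.
#'
#' @param seed master seed.
#' @param n_patients number of patients (default 7).
#' @param conditions session conditions.
#' @param truth ground-truth overrides (named list).
#' @param models model variants to fit (subset of M1..M6; `character()`
#'   skips fitting).
#' @param n_draws,n_burn,n_chains,thin MCMC settings.
#' @param n_perm cluster-permutation count.
#' @param z_thresh per-window threshold (default `z_threshold(0.05, 4)`).
#' @param width_ms,step_ms window grid settings.
#' @param out_dir output directory.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(seed = 1, n_patients = 7,
                            conditions = c("off", "cdbs", "adbs"),
                            truth = list(), models = c("M1", "M3"),
                            n_draws = 1000, n_burn = 1000, n_chains = 2,
                            thin = 2, n_perm = 1000,
                            z_thresh = z_threshold(0.05, 4),
                            width_ms = 100, step_ms = 10,
                            out_dir = tempfile("adbsddm_run_")) {
  structure(as.list(environment()), class = "run_config")
}

.log_line <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(line, "\n", sep = "", file = con, append = TRUE)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generate -> simulate closed-loop stimulation -> label windows and run
#' the four sliding-window cluster tests -> fit the requested models ->
#' cohort statistics -> summary report.  Every stage's outputs are
#' persisted under `config$out_dir`; the log records every seed,
#' threshold, and window setting used.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the cohort, cluster results, fits, and
#'   stats table; side effect: files under `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.txt")
  cat("", file = logf)
  .log_line(logf, "pipeline start; master seed = ", config$seed)

  truth <- do.call(default_ground_truth, config$truth)
  cohort <- generate_cohort(config$seed, config$n_patients,
                            config$conditions, truth)
  readr::write_csv(cohort$trials, file.path(config$out_dir, "trials.csv"))
  .log_line(logf, "cohort generated: ", nrow(cohort$trials), " trials")

  # --- sliding-window stimulation analysis on the adaptive sessions -----
  clusters <- list()
  if ("adbs" %in% config$conditions) {
    lab <- cohort_window_labels(cohort, width_ms = config$width_ms,
                                step_ms = config$step_ms)
    for (align in c("cue", "response")) {
      for (fac in c("coherence", "instruction")) {
        eff <- stim_contrast(lab[[align]]$trials, lab[[align]]$labels, fac)
        cl <- cluster_permutation(eff, z_thresh = config$z_thresh,
                                  n_perm = config$n_perm,
                                  seed = config$seed + 101L)
        key <- paste(align, fac, sep = "_")
        clusters[[key]] <- cl
        readr::write_csv(cl, file.path(config$out_dir,
                                       paste0("clusters_", key, ".csv")))
        .log_line(logf, "cluster test ", key, ": ",
                  sum(cl$significant), " significant cluster(s), z_thresh=",
                  config$z_thresh, ", n_perm=", config$n_perm)
      }
    }
  }

  # --- model fits --------------------------------------------------------
  fits <- list()
  for (mname in config$models) {
    sub <- switch(mname,
      M1 = , M5 = , M6 = cohort$trials[cohort$trials$condition == "off", ],
      M2 = , M3 = cohort$trials[cohort$trials$condition == "adbs", ],
      M4 = {
        tr <- cohort$trials[cohort$trials$condition %in% c("off", "cdbs"), ]
        tr$stim <- as.integer(tr$condition == "cdbs")
        tr
      })
    if (mname %in% c("M5", "M6")) {
      covs <- lapply(seq_len(config$n_patients), function(p)
        add_beta_covariates(cohort$sessions[[p]]$off))
      sub <- do.call(rbind, lapply(seq_along(covs), function(p) {
        x <- covs[[p]]; x$patient <- p; x$condition <- "off"; x$session <- NA
        x
      }))
    }
    model <- build_model(sub, mname)
    fit <- fit_ddm(model, config$n_draws, config$n_burn, config$n_chains,
                   config$thin, seed = config$seed + 211L)
    fits[[mname]] <- fit
    .log_line(logf, "fit ", mname, ": DIC=", round(fit$dic$dic, 1),
              " max R-hat=", round(max(fit$rhat, na.rm = TRUE), 3),
              " seed=", config$seed + 211L)
    cs <- coef_summary(fit)
    readr::write_csv(cs, file.path(config$out_dir,
                                   paste0("coefficients_", mname, ".csv")))
  }

  # --- behavioural cohort statistics ------------------------------------
  stats_tab <- behavior_stats(cohort$trials)
  readr::write_csv(stats_tab, file.path(config$out_dir, "stats.csv"))

  report <- summarize_run(cohort, clusters, fits, stats_tab, config)
  writeLines(report, file.path(config$out_dir, "report.md"))
  .log_line(logf, "pipeline done")
  invisible(list(cohort = cohort, clusters = clusters, fits = fits,
                 stats = stats_tab, config = config))
}

#' Per-alignment window labels for a cohort's adaptive sessions
#'
#' Builds the cue- and response-aligned stimulation label matrices from
#' each patient's effective-stimulation mask, concatenated across
#' patients to match the pooled trial rows.
#'
#' @param cohort an `adbs_cohort` with sessions kept.
#' @param width_ms,step_ms grid settings.
#' @return List with elements `cue` and `response`, each holding
#'   `trials` and the matching `labels` matrix.
#' @export
cohort_window_labels <- function(cohort, width_ms = 100, step_ms = 10) {
  stopifnot(inherits(cohort, "adbs_cohort"), !is.null(cohort$sessions))
  grids <- list(cue = window_grid("cue", width_ms, step_ms),
                response = window_grid("response", width_ms, step_ms))
  out <- list()
  for (align in names(grids)) {
    trial_list <- list(); label_list <- list()
    for (p in seq_along(cohort$sessions)) {
      ses <- cohort$sessions[[p]]$adbs
      if (is.null(ses)) next
      mask <- effective_stim_mask(ses$stim)
      ev <- if (align == "cue") ses$envelope$cue_samples
            else ses$envelope$resp_samples
      lb <- window_stim_labels(mask, ev, ses$envelope$fs, grids[[align]])
      tr <- ses$trials
      tr$patient <- p
      trial_list[[p]] <- tr
      label_list[[p]] <- lb
    }
    out[[align]] <- list(trials = do.call(rbind, trial_list),
                         labels = do.call(rbind, label_list),
                         grid = grids[[align]])
  }
  out
}

#' Coefficient summary table for a fit
#'
#' @param fit a `ddm_fit`.
#' @return Tibble with posterior mean, SD, central 95% interval, and the
#'   posterior probability of the coefficient exceeding zero.
#' @export
coef_summary <- function(fit) {
  cn <- fit$model$coef_names
  if (!length(cn)) return(tibble::tibble())
  do.call(rbind, lapply(cn, function(p) {
    d <- get_draws(fit, p)
    tibble::tibble(label = fit$model$b_labels[[p]], coefficient = p,
                   mean = mean(d), sd = stats::sd(d),
                   q2.5 = stats::quantile(d, 0.025, names = FALSE),
                   q97.5 = stats::quantile(d, 0.975, names = FALSE),
                   p_greater_0 = mean(d > 0))
  }))
}

#' Standard behavioural contrasts for a cohort
#'
#' Off-stimulation coherence and instruction effects on RT and accuracy
#' (signed-rank against zero) and, when stimulation sessions are present,
#' the percent change of both effects under stimulation versus off.
#'
#' @param trials cohort trial table.
#' @return Tibble of test results.
#' @export
behavior_stats <- function(trials) {
  keep <- !trials$omission & !is.na(trials$rt_s)
  tr <- trials[keep, ]
  off <- tr[tr$condition == "off", ]
  rows <- list()
  per_patient <- function(d, f, lv, col, fun = stats::median) {
    vapply(sort(unique(d$patient)), function(p) {
      i <- d$patient == p
      fun(d[[col]][i & d[[f]] == lv[1]]) - fun(d[[col]][i & d[[f]] == lv[2]])
    }, numeric(1))
  }
  add <- function(label, x, y = NULL) {
    w <- wilcoxon_signed_rank(x, y)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      test = label, n = w$n, median_effect = stats::median(x - (y %||% 0)),
      z = w$z, p = w$p)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  if (nrow(off)) {
    add("off: RT low - high coherence (s)",
        per_patient(off, "coherence", c("low", "high"), "rt_s"))
    add("off: RT accuracy - speed instruction (s)",
        per_patient(off, "instruction", c("accuracy", "speed"), "rt_s"))
    acc_tab <- off
    acc_tab$acc <- as.numeric(acc_tab$accuracy)
    add("off: accuracy low - high coherence",
        per_patient(acc_tab, "coherence", c("low", "high"), "acc", mean))
  }
  for (cond in intersect(c("adbs", "cdbs"), unique(tr$condition))) {
    ec <- effect_change(tr, "coherence", list(cond, "off"))
    add(paste0(cond, ": % change coherence effect"), ec$percent_change)
    ei <- effect_change(tr, "instruction", list(cond, "off"))
    add(paste0(cond, ": % change instruction effect"), ei$percent_change)
  }
  do.call(rbind, rows)
}

summarize_run <- function(cohort, clusters, fits, stats_tab, config) {
  c(
    "# Synthetic cohort analysis report",
    "",
    sprintf("- master seed: %d", config$seed),
    sprintf("- trials: %d (%d patients x %d conditions x %d)",
            nrow(cohort$trials), config$n_patients,
            length(config$conditions), cohort$truth$n_trials),
    "",
    "## Sliding-window cluster tests",
    if (length(clusters)) {
      unlist(lapply(names(clusters), function(k) {
        cl <- clusters[[k]]
        sig <- cl[cl$significant, , drop = FALSE]
        if (nrow(sig))
          sprintf("- %s: significant cluster windows %d-%d (mass %.1f, p = %.3f)",
                  k, sig$start[1], sig$end[1], sig$mass[1], sig$p_value[1])
        else sprintf("- %s: no significant cluster", k)
      }))
    } else "- (no adaptive sessions)",
    "",
    "## Model fits",
    if (length(fits)) {
      unlist(lapply(names(fits), function(m) {
        f <- fits[[m]]
        cs <- coef_summary(f)
        c(sprintf("### %s (DIC %.1f, max R-hat %.3f)", m, f$dic$dic,
                  max(f$rhat, na.rm = TRUE)),
          sprintf("- %s (%s): mean %.3f, P(>0) = %.3f",
                  cs$coefficient, cs$label, cs$mean, cs$p_greater_0))
      }))
    } else "- (no fits requested)",
    "",
    "## Behavioural statistics",
    sprintf("- %s: median %.3f, Z = %.2f, p = %.4f",
            stats_tab$test, stats_tab$median_effect, stats_tab$z, stats_tab$p)
  )
}

# ---------------------------------------------------------------------------
# Cohort file round-trip (plain-text formats)

# format double columns with 17 significant digits so values survive the
# CSV round trip bit-identically
.fmt_doubles <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      x <- sprintf("%.17g", df[[nm]])
      x[is.na(df[[nm]])] <- NA
      df[[nm]] <- x
    }
  }
  df
}

#' Write a cohort to a directory of plain-text files
#'
#' `trials.csv` (the fixed analysis header plus generative-truth
#' columns), `subjects.csv`, `ground_truth.json`, and optionally one
#' `session_<patient>_<condition>.csv` per kept session (sample, envelope
#' value, raw LFP, trigger state, voltage fraction) with the sampling
#' rate and event samples in `sessions.json`.
#'
#' @param cohort an `adbs_cohort`.
#' @param dir output directory.
#' @param include_series write envelope/stimulation series (default
#'   FALSE; they are large).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, include_series = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(.fmt_doubles(cohort$trials), file.path(dir, "trials.csv"))
  readr::write_csv(.fmt_doubles(cohort$subjects),
                   file.path(dir, "subjects.csv"))
  jsonlite::write_json(list(truth = unclass(cohort$truth), seed = cohort$seed),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (include_series && !is.null(cohort$sessions)) {
    meta <- list()
    for (p in seq_along(cohort$sessions)) {
      for (cond in names(cohort$sessions[[p]])) {
        ses <- cohort$sessions[[p]][[cond]]
        key <- sprintf("session_%d_%s", p, cond)
        df <- tibble::tibble(envelope = ses$envelope$values,
                             lfp = ses$envelope$lfp)
        if (!is.null(ses$stim)) {
          df$trigger <- ses$stim$trigger_state
          df$voltage <- ses$stim$voltage_fraction
        }
        readr::write_csv(.fmt_doubles(df), file.path(dir, paste0(key, ".csv")))
        meta[[key]] <- list(fs = ses$envelope$fs,
                            cue_samples = ses$envelope$cue_samples,
                            resp_samples = ses$envelope$resp_samples,
                            condition = cond, patient = p,
                            threshold = ses$threshold)
      }
    }
    jsonlite::write_json(meta, file.path(dir, "sessions.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory.
#' @return An `adbs_cohort` (sessions present only if series were
#'   written).
#' @export
read_cohort <- function(dir) {
  # base read.csv: its strtod-based parser is correctly rounding, so
  # 17-digit decimals come back bit-identical
  trials <- tibble::as_tibble(utils::read.csv(file.path(dir, "trials.csv")))
  for (nm in c("patient", "session", "block_index", "trial_index",
               "accuracy", "stim"))
    if (nm %in% names(trials)) trials[[nm]] <- as.integer(trials[[nm]])
  subjects <- tibble::as_tibble(utils::read.csv(file.path(dir,
                                                          "subjects.csv")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  truth <- do.call(default_ground_truth, as.list(gt$truth))
  sessions <- NULL
  sfile <- file.path(dir, "sessions.json")
  if (file.exists(sfile)) {
    meta <- jsonlite::read_json(sfile, simplifyVector = TRUE)
    sessions <- list()
    for (key in names(meta)) {
      m <- meta[[key]]
      df <- utils::read.csv(file.path(dir, paste0(key, ".csv")))
      env <- new_beta_envelope(df$envelope, m$fs,
                               as.integer(m$cue_samples),
                               as.integer(m$resp_samples))
      env$lfp <- df$lfp
      stim <- if ("trigger" %in% names(df))
        new_stim_trace(m$fs, df$trigger, df$voltage) else NULL
      p <- m$patient
      if (length(sessions) < p || is.null(sessions[p][[1]]))
        sessions[[p]] <- list()
      tr <- trials[trials$patient == p & trials$condition == m$condition, ]
      sessions[[p]][[m$condition]] <-
        structure(list(trials = tr, envelope = env, stim = stim,
                       condition = m$condition, threshold = m$threshold),
                  class = "adbs_session")
    }
  }
  structure(list(trials = trials, sessions = sessions, subjects = subjects,
                 truth = truth, seed = gt$seed),
            class = "adbs_cohort")
}
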