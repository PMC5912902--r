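#' Regression design for the hierarchical DDM
#'
#' Named model variants linking trial-wise regressors to the decision
#' threshold `a`, drift rate `v`, and non-decision time `t`:
#'
#' * `M1` baseline: `a ~ Instr + Coh`, `v ~ Coh`
#' * `M2` stimulation interaction (9 coefficients):
#'   `a ~ Instr + Coh + Stim + Instr:Stim + Coh:Stim`,
#'   `v ~ Coh + Stim + Coh:Stim`, `t ~ Stim`
#' * `M3` post-hoc split: `a ~ Instr + Coh_Stim + Coh_noStim + Stim`,
#'   `v ~ Coh`
#' * `M4` as `M3` with `Stim` marking the continuous-stimulation session
#' * `M5` cue-induced beta decrease: `a ~ Instr + Coh + Betadecrease`,
#'   `v ~ Coh`
#' * `M6` late beta: `a ~ Instr + Coh + Beta_LC + Beta_HC`, `v ~ Coh`
#'
#' Regressor coding: `Instr` 0 = accuracy, 1 = speed; `Coh` 0 = high,
#' 1 = low; `Stim` 0 = off, 1 = on; continuous regressors are z-scored
#' within subject before entry.  A custom design may be given as named
#' character vectors.
#'
#' @param name one of `"M1"` to `"M6"`, or `"custom"`.
#' @param a,v,t regressor names for a custom design.
#' @return List of class `ddm_spec`.
#' @export
ddm_spec <- function(name = c("M1", "M2", "M3", "M4", "M5", "M6", "custom"),
                     a = character(), v = character(), t = character()) {
  name <- match.arg(name)
  designs <- list(
    M1 = list(a = c("Instr", "Coh"), v = "Coh", t = character()),
    M2 = list(a = c("Instr", "Coh", "Stim", "Instr:Stim", "Coh:Stim"),
              v = c("Coh", "Stim", "Coh:Stim"), t = "Stim"),
    M3 = list(a = c("Instr", "Coh_Stim", "Coh_noStim", "Stim"),
              v = "Coh", t = character()),
    M4 = list(a = c("Instr", "Coh_Stim", "Coh_noStim", "Stim"),
              v = "Coh", t = character()),
    M5 = list(a = c("Instr", "Coh", "Betadecrease"), v = "Coh",
              t = character()),
    M6 = list(a = c("Instr", "Coh", "Beta_LC", "Beta_HC"), v = "Coh",
              t = character())
  )
  d <- if (name == "custom") list(a = a, v = v, t = t) else designs[[name]]
  structure(c(list(name = name), d), class = "ddm_spec")
}

# map regressor names to (possibly derived) numeric trial columns
.regressor_column <- function(trials, reg) {
  base <- list(
    Instr = function(tr) as.numeric(tr$instruction == "speed"),
    Coh = function(tr) as.numeric(tr$coherence == "low"),
    Stim = function(tr) as.numeric(tr$stim),
    Betadecrease = function(tr) tr$beta_decrease_z,
    Beta_LC = function(tr) tr$beta_lc_z,
    Beta_HC = function(tr) tr$beta_hc_z
  )
  needs <- list(Instr = "instruction", Coh = "coherence", Stim = "stim",
                Betadecrease = "beta_decrease_z", Beta_LC = "beta_lc_z",
                Beta_HC = "beta_hc_z")
  get1 <- function(r) {
    if (r == "Coh_Stim") return(get1("Coh") * get1("Stim"))
    if (r == "Coh_noStim") return(get1("Coh") * (1 - get1("Stim")))
    parts <- strsplit(r, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2) return(get1(parts[1]) * get1(parts[2]))
    if (!r %in% names(base)) stop("unknown regressor: ", r)
    col <- needs[[r]]
    if (!col %in% names(trials))
      stop("regressor `", r, "` needs missing trial column `", col, "`")
    base[[r]](trials)
  }
  get1(reg)
}

#' Default group-level priors
#'
#' Weakly-informative defaults: truncated normals on the group means
#' (`mu_a ~ N(1.5, 0.75^2)` on the positive line,
#' `mu_v ~ N(2, 3^2)`, `mu_t ~ N(0.4, 0.2^2)` non-negative), half-normals
#' on the group SDs, and `N(0, 2^2)` on every regression coefficient.
#' All hyperparameters can be overridden.
#'
#' @param ... named overrides.
#' @return Named list of prior hyperparameters.
#' @export
ddm_priors <- function(...) {
  pr <- list(mu_a_mean = 1.5, mu_a_sd = 0.75,
             mu_v_mean = 2, mu_v_sd = 3,
             mu_t_mean = 0.4, mu_t_sd = 0.2,
             sig_a_scale = 1, sig_v_scale = 1, sig_t_scale = 0.3,
             beta_sd = 2)
  over <- list(...)
  bad <- setdiff(names(over), names(pr))
  if (length(bad)) stop("unknown prior fields: ", paste(bad, collapse = ", "))
  pr[names(over)] <- over
  pr
}

#' Build a hierarchical DDM regression model
#'
#' Wires the trial table to the Wiener first-passage-time likelihood with
#' the start point fixed at `z = 0.5` (responses coded by accuracy:
#' correct responses absorb at the upper boundary).  Omissions and trials
#' with RT < 0.25 s are excluded.  Trials excluded from a beta regressor
#' (see [late_beta()]) stay in the likelihood with the regressor at zero.
#'
#' @param trials trial table (one subject column `patient`).
#' @param spec a [ddm_spec()] (or variant name as a string).
#' @param priors from [ddm_priors()].
#' @param rt_min lower RT cutoff in seconds (default 0.25).
#' @param tol WFPT series tolerance.
#' @return Object of class `ddm_model`.
#' @export
build_model <- function(trials, spec = "M1", priors = ddm_priors(),
                        rt_min = 0.25, tol = 1e-7) {
  if (is.character(spec)) spec <- ddm_spec(spec)
  stopifnot(inherits(spec, "ddm_spec"))
  keep <- !trials$omission & !is.na(trials$rt_s) & trials$rt_s >= rt_min
  trials <- trials[keep, ]
  trials <- trials[order(trials$patient), ]

  Xa <- vapply(spec$a, function(r) .regressor_column(trials, r),
               numeric(nrow(trials)))
  Xv <- vapply(spec$v, function(r) .regressor_column(trials, r),
               numeric(nrow(trials)))
  Xt <- vapply(spec$t, function(r) .regressor_column(trials, r),
               numeric(nrow(trials)))
  dim_fix <- function(X, nm) {
    X <- matrix(as.numeric(X), nrow = nrow(trials))
    colnames(X) <- nm
    X
  }
  Xa <- dim_fix(Xa, spec$a); Xv <- dim_fix(Xv, spec$v); Xt <- dim_fix(Xt, spec$t)

  subs <- unique(trials$patient)
  subj <- match(trials$patient, subs)
  subj_start <- c(0L, cumsum(tabulate(subj, length(subs))))

  coef_names <- c(if (length(spec$a)) paste0("a_", spec$a),
                  if (length(spec$v)) paste0("v_", spec$v),
                  if (length(spec$t)) paste0("t_", spec$t))
  b_labels <- if (length(coef_names))
    stats::setNames(paste0("b", seq_along(coef_names)), coef_names)
  else character()

  structure(list(
    spec = spec, priors = priors, tol = tol,
    rt = trials$rt_s, upper = as.integer(trials$accuracy),
    subj_start = as.integer(subj_start), subjects = subs,
    Xa = Xa, Xv = Xv, Xt = Xt,
    coef_names = coef_names, b_labels = b_labels,
    trials = trials
  ), class = "ddm_model")
}

#' @export
print.ddm_model <- function(x, ...) {
  cat("Hierarchical DDM model", x$spec$name, "-", length(x$rt), "trials,",
      length(x$subjects), "subjects,", length(x$coef_names),
      "regression coefficients\n")
  if (length(x$coef_names))
    cat("  ", paste(x$b_labels, "=", names(x$b_labels), collapse = ", "), "\n")
  invisible(x)
}

# crude per-subject starting values (logistic-accuracy drift given a
# provisional threshold; non-decision time below the fastest trial)
.ddm_init <- function(model, jitter = 0) {
  S <- length(model$subjects)
  a0 <- v0 <- t0 <- numeric(S)
  for (s in seq_len(S)) {
    i <- (model$subj_start[s] + 1):model$subj_start[s + 1]
    acc <- min(max(mean(model$upper[i]), 0.6), 0.95)
    a0[s] <- 1.5
    v0[s] <- stats::qlogis(acc) / a0[s]
    t0[s] <- max(0.1, 0.8 * min(model$rt[i]))
  }
  th <- c(mean(a0), mean(v0), mean(t0), log(0.2), log(0.3), log(0.05),
          a0, v0, t0, rep(0, length(model$coef_names)))
  if (jitter > 0) {
    set_i <- c(1:3, 6 + seq_len(3 * S))
    th[set_i] <- th[set_i] * (1 + stats::rnorm(length(set_i), 0, jitter))
    th[4:6] <- th[4:6] + stats::rnorm(3, 0, jitter)
  }
  # keep t0 safely below each subject's fastest trial
  for (s in seq_len(S)) {
    i <- (model$subj_start[s] + 1):model$subj_start[s + 1]
    th[6 + 2 * S + s] <- min(th[6 + 2 * S + s], 0.9 * min(model$rt[i]))
    th[6 + s] <- max(th[6 + s], 0.4)
  }
  th
}

.param_names <- function(model) {
  S <- length(model$subjects)
  c("mu_a", "mu_v", "mu_t", "sigma_a", "sigma_v", "sigma_t",
    paste0("a[", model$subjects, "]"), paste0("v[", model$subjects, "]"),
    paste0("t[", model$subjects, "]"), model$coef_names)
}

#' Fit a hierarchical DDM model by MCMC
#'
#' Single-site adaptive random-walk Metropolis over group means and SDs,
#' subject-level parameters, and group-level regression coefficients
#' (trial-wise coefficients are estimated at the group level only).
#' Chains are run from jittered starting values; convergence is assessed
#' with the Gelman-Rubin statistic and a warning is issued when any
#' parameter has R-hat >= 1.1.
#'
#' @param model a [build_model()] object.
#' @param n_draws posterior draws kept per chain (default 1500).
#' @param n_burn burn-in sweeps (default 1500, with proposal adaptation).
#' @param n_chains number of chains (>= 2, default 2).
#' @param thin thinning interval (default 2).
#' @param seed integer seed.
#' @return Object of class `ddm_fit`: `draws` (array draws x chains x
#'   parameters, group SDs on the natural scale), `deviance`, `dic`,
#'   `rhat`, `model`.
#' @export
fit_ddm <- function(model, n_draws = 1500, n_burn = 1500, n_chains = 2,
                    thin = 2, seed = 1) {
  stopifnot(inherits(model, "ddm_model"))
  if (n_chains < 2) stop("need at least 2 chains")
  S <- length(model$subjects)
  P <- 6 + 3 * S + length(model$coef_names)
  scale0 <- c(0.05, 0.1, 0.02, rep(0.2, 3),
              rep(0.08, S), rep(0.15, S), rep(0.015, S),
              rep(0.05, length(model$coef_names)))
  n_iter <- n_burn + n_draws * thin

  draws <- array(NA_real_, c(n_draws, n_chains, P))
  dev <- matrix(NA_real_, n_draws, n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + 7919L * (ch - 1L))
    init <- .ddm_init(model, jitter = if (ch == 1) 0 else 0.05)
    res <- ddm_mcmc_cpp(model$rt, model$upper, model$subj_start,
                        model$Xa, model$Xv, model$Xt,
                        model$priors, init, scale0,
                        n_iter, n_burn, thin, model$tol)
    draws[, ch, ] <- res$draws
    dev[, ch] <- res$deviance
  }
  draws[, , 4:6] <- exp(draws[, , 4:6])     # log sigma -> sigma
  dimnames(draws) <- list(NULL, NULL, .param_names(model))

  rh <- apply(draws, 3, .rhat_matrix)
  fit <- structure(list(draws = draws, deviance = dev,
                        rhat = rh, model = model,
                        n_draws = n_draws, n_chains = n_chains,
                        seed = seed),
                   class = "ddm_fit")
  fit$dic <- dic(fit)
  if (any(rh >= 1.1, na.rm = TRUE))
    warning("convergence not reached: max R-hat = ",
            round(max(rh, na.rm = TRUE), 3))
  fit
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Hierarchical DDM fit (", x$model$spec$name, "): ",
      x$n_draws, " draws x ", x$n_chains, " chains, DIC = ",
      round(x$dic$dic, 1), ", max R-hat = ",
      round(max(x$rhat, na.rm = TRUE), 3), "\n", sep = "")
  mu <- apply(x$draws, 3, mean)
  show <- c("mu_a", "mu_v", "mu_t", x$model$coef_names)
  print(round(mu[show], 3))
  invisible(x)
}

#' Extract posterior draws of one parameter
#'
#' @param fit a `ddm_fit`.
#' @param par parameter name (see `dimnames(fit$draws)[[3]]`); regression
#'   coefficients may also be addressed by label `"b1"`, `"b2"`, ...
#' @return Numeric vector of pooled draws (all chains).
#' @export
get_draws <- function(fit, par) {
  stopifnot(inherits(fit, "ddm_fit"))
  nm <- dimnames(fit$draws)[[3]]
  if (grepl("^b[0-9]+$", par)) {
    hit <- names(fit$model$b_labels)[fit$model$b_labels == par]
    if (!length(hit)) stop("no coefficient labelled ", par)
    par <- hit
  }
  if (!par %in% nm) stop("unknown parameter: ", par)
  as.vector(fit$draws[, , par])
}

#' Posterior probability of a directional hypothesis
#'
#' Fraction of posterior draws satisfying the direction; comparisons
#' between two posteriors use draw-wise differences.  The decision rule
#' used throughout is significance at probability >= 0.95.
#'
#' @param draws numeric vector of posterior draws of one quantity.
#' @param direction `">"` or `"<"`.
#' @param ref reference: a scalar (default 0) or a second vector of draws
#'   of equal length.
#' @return Probability in `[0, 1]`.
#' @export
posterior_probability <- function(draws, direction = c(">", "<"), ref = 0) {
  direction <- match.arg(direction)
  if (!length(draws)) stop("empty draws")
  if (length(draws) < 1000)
    warning("fewer than 1000 draws; probability estimate is coarse")
  d <- if (length(ref) > 1) {
    if (length(ref) != length(draws)) stop("draws/ref length mismatch")
    draws - ref
  } else draws - ref
  if (direction == ">") mean(d > 0) else mean(d < 0)
}

# reconstruct per-trial (a, v, t) from one parameter vector
.trial_params <- function(model, theta) {
  S <- length(model$subjects)
  subj <- rep(seq_len(S), diff(model$subj_start))
  pa <- ncol(model$Xa); pv <- ncol(model$Xv); pt <- ncol(model$Xt)
  b <- theta[seq_len(pa + pv + pt) + 6 + 3 * S]
  a <- theta[6 + subj] +
    if (pa) as.vector(model$Xa %*% b[seq_len(pa)]) else 0
  v <- theta[6 + S + subj] +
    if (pv) as.vector(model$Xv %*% b[pa + seq_len(pv)]) else 0
  t <- theta[6 + 2 * S + subj] +
    if (pt) as.vector(model$Xt %*% b[pa + pv + seq_len(pt)]) else 0
  list(a = a, v = v, t = t)
}

#' Deviance information criterion
#'
#' `DIC = D(theta_bar) + 2 pD` with `pD = Dbar - D(theta_bar)`: the
#' posterior-mean deviance plus twice the effective number of parameters.
#' Lower values indicate stronger evidence.
#'
#' @param fit a `ddm_fit`.
#' @return List with `dic`, `p_d`, `d_bar`, `d_hat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  d_bar <- mean(fit$deviance)
  theta <- apply(fit$draws, 3, mean)
  theta[4:6] <- log(theta[4:6])       # back to sampler scale (unused in ll)
  tp <- .trial_params(fit$model, theta)
  d_hat <- -2 * ddm_loglik_cpp(fit$model$rt, fit$model$upper,
                               tp$a, tp$v, tp$t, fit$model$tol)
  p_d <- d_bar - d_hat
  list(dic = d_hat + 2 * p_d, p_d = p_d, d_bar = d_bar, d_hat = d_hat)
}

# Gelman-Rubin on a draws x chains matrix
.rhat_matrix <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (m < 2 || n < 4) return(NA_real_)
  means <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n * (1 + 1 / m)) / W)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per parameter, from at least two
#' chains.
#'
#' @param x a `ddm_fit`, or a draws x chains matrix for one parameter.
#' @return Named numeric vector (or scalar).
#' @export
rhat <- function(x) {
  if (inherits(x, "ddm_fit")) return(x$rhat)
  if (is.matrix(x)) {
    if (ncol(x) < 2) stop("need at least 2 chains")
    return(.rhat_matrix(x))
  }
  stop("`x` must be a ddm_fit or a draws x chains matrix")
}

#' Posterior predictive trial tables
#'
#' Simulates replicated datasets from evenly spaced posterior draws,
#' carrying over the observed condition labels.
#'
#' @param fit a `ddm_fit`.
#' @param n_rep number of replicated datasets (default 50).
#' @param seed integer seed.
#' @param dt forward-simulation step (default 1e-3; predictive checks do
#'   not need the fine step used for likelihood validation).
#' @return List of trial tibbles, one per posterior draw.
#' @export
posterior_predict <- function(fit, n_rep = 50, seed = 1, dt = 1e-3) {
  stopifnot(inherits(fit, "ddm_fit"))
  set.seed(seed)
  total <- fit$n_draws * fit$n_chains
  pick <- round(seq(1, total, length.out = n_rep))
  flat <- matrix(fit$draws, nrow = total)
  colnames(flat) <- dimnames(fit$draws)[[3]]
  trials <- fit$model$trials
  lapply(pick, function(i) {
    theta <- flat[i, ]
    theta[4:6] <- log(theta[4:6])
    tp <- .trial_params(fit$model, theta)
    sim <- ddm_simulate_cpp(tp$a, tp$v, tp$t, 0.5, dt, 20)
    out <- trials
    out$rt_s <- sim$rt
    out$accuracy <- as.integer(sim$upper)
    out
  })
}

#' Quantile-probability summary
#'
#' Pairs RT quantiles with cumulative response probabilities per
#' condition: the x-coordinate is percentile x accuracy for correct
#' responses and percentile x (1 - accuracy) for errors.  Error quantiles
#' are reported only where the error count permits (at least
#' `min_errors`).  With posterior predictive replicates, the predictive
#' mean and spread (SD over replicates) are attached.
#'
#' @param observed trial table with `rt_s`, `accuracy`, and the condition
#'   columns.
#' @param predicted optional list of replicated trial tables
#'   ([posterior_predict()]).
#' @param percentiles percent points (default 10, 30, 50, 70, 90).
#' @param by condition columns (default instruction x coherence).
#' @param min_errors minimum error trials for error quantiles.
#' @return Tibble with one row per condition x response type x percentile.
#' @export
qp_summary <- function(observed, predicted = NULL,
                       percentiles = c(10, 30, 50, 70, 90),
                       by = c("instruction", "coherence"), min_errors = 5) {
  obs <- observed[!is.na(observed$rt_s) & !is.na(observed$accuracy), ]
  if (!nrow(obs)) stop("empty condition")
  key <- interaction(obs[by], drop = TRUE, sep = "/")
  one <- function(rt, acc, lab) {
    p_corr <- mean(acc == 1)
    rows <- list()
    for (resp in c(1, 0)) {
      rt_r <- rt[acc == resp]
      if (resp == 0 && length(rt_r) < min_errors) next
      if (!length(rt_r)) next
      prob <- if (resp == 1) p_corr else 1 - p_corr
      rows[[length(rows) + 1]] <- tibble::tibble(
        condition = lab,
        response = if (resp == 1) "correct" else "error",
        percentile = percentiles,
        cum_prob = percentiles / 100 * prob,
        rt_q = stats::quantile(rt_r, percentiles / 100, names = FALSE)
      )
    }
    do.call(rbind, rows)
  }
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    i <- key == lv
    one(obs$rt_s[i], obs$accuracy[i], lv)
  }))
  if (!is.null(predicted)) {
    preds <- lapply(predicted, function(rep) {
      rep <- rep[!is.na(rep$rt_s) & !is.na(rep$accuracy), ]
      k <- interaction(rep[by], drop = TRUE, sep = "/")
      do.call(rbind, lapply(levels(k), function(lv) {
        i <- k == lv
        one(rep$rt_s[i], rep$accuracy[i], lv)
      }))
    })
    id <- function(d) paste(d$condition, d$response, d$percentile)
    ref <- id(out)
    pm <- sapply(preds, function(d) d$rt_q[match(ref, id(d))])
    pp <- sapply(preds, function(d) d$cum_prob[match(ref, id(d))])
    out$rt_pred_mean <- rowMeans(pm, na.rm = TRUE)
    out$rt_pred_sd <- apply(pm, 1, stats::sd, na.rm = TRUE)
    out$cum_prob_pred <- rowMeans(pp, na.rm = TRUE)
  }
  out
}
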