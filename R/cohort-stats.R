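#' Wilcoxon signed-rank test with normal-approximation Z
#'
#' Matched-pairs signed-rank test reporting Wilcoxon's Z (normal
#' approximation with midranks for ties, zero differences dropped, and a
#' continuity correction) and a two-sided p-value.  For n <= 12 non-zero
#' differences without ties the p-value is computed by exact enumeration
#' of all sign assignments.  The sign of Z follows the sign of the median
#' difference `x - y`.
#'
#' @param x numeric vector.
#' @param y optional paired vector (default zero, i.e. a one-sample test
#'   of `x` against 0).
#' @param exact_max largest n for which exact enumeration is used.
#' @return List with `z`, `p`, `n` (non-zero pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 12) {
  if (is.null(y)) y <- rep(0, length(x))
  stopifnot(length(x) == length(y))
  d <- x - y
  if (any(!is.finite(d))) stop("differences must be finite")
  d <- d[d != 0]                      # Wilcoxon's zero-drop rule
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; test degenerate")
    return(list(z = 0, p = 1, n = 0L, method = "degenerate"))
  }
  if (n < 4) warning("fewer than 4 non-zero pairs; test has no power")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  ew <- n * (n + 1) / 4
  ties <- table(r)
  varw <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- sign(w_pos - ew) * 0.5
  z <- if (varw > 0) (w_pos - ew - cc) / sqrt(varw) else 0

  has_ties <- any(duplicated(abs(d)))
  if (n <= exact_max && !has_ties) {
    # exact two-sided p: enumerate all 2^n sign patterns of the ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wdist <- as.vector(signs %*% r)
    p_ge <- mean(wdist >= w_pos)
    p_le <- mean(wdist <= w_pos)
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(z = z, p = p, n = n, method = method)
}

#' Paired condition effect per patient, in percent or absolute units
#'
#' Computes, per patient, the effect of a within-session factor (e.g. the
#' low-minus-high-coherence RT difference) under two conditions and the
#' change between them, as percent change
#' `(effect_A - effect_B) / effect_B * 100` (controlling for overall RT
#' changes) and as absolute change.
#'
#' @param trials cohort trial table with `patient`, `condition`, `rt_s`,
#'   `omission`, and the factor column.
#' @param factor `"coherence"` (low - high) or `"instruction"`
#'   (accuracy - speed).
#' @param conditions length-2: the comparison condition(s) and the
#'   baseline condition; the first element may be a vector of conditions
#'   pooled together (e.g. `c("adbs", "cdbs")`).
#' @param value summary statistic per cell (default median RT).
#' @return Tibble per patient with `effect_on`, `effect_off`,
#'   `percent_change`, `abs_change`.
#' @export
effect_change <- function(trials, factor = c("coherence", "instruction"),
                          conditions = list("cdbs", "off"),
                          value = stats::median) {
  factor <- match.arg(factor)
  lv <- if (factor == "coherence") c("low", "high") else c("accuracy", "speed")
  keep <- !trials$omission & !is.na(trials$rt_s)
  trials <- trials[keep, ]
  eff <- function(sub) {
    a <- value(sub$rt_s[sub[[factor]] == lv[1]])
    b <- value(sub$rt_s[sub[[factor]] == lv[2]])
    a - b
  }
  patients <- sort(unique(trials$patient))
  on_set <- conditions[[1]]; off_set <- conditions[[2]]
  res <- lapply(patients, function(p) {
    on <- trials[trials$patient == p & trials$condition %in% on_set, ]
    off <- trials[trials$patient == p & trials$condition %in% off_set, ]
    if (!nrow(on) || !nrow(off)) stop("patient ", p, " missing a condition")
    e_on <- eff(on); e_off <- eff(off)
    tibble::tibble(patient = p, effect_on = e_on, effect_off = e_off,
                   percent_change = (e_on - e_off) / e_off * 100,
                   abs_change = e_on - e_off)
  })
  do.call(rbind, res)
}

#' Within-subject correlation with group-level inference
#'
#' Spearman rank correlation between two trial-wise variables within each
#' subject, Fisher r-to-z transformed, then tested against zero across
#' subjects with the signed-rank test.
#'
#' @param x,y numeric trial vectors.
#' @param subject per-trial subject identifier.
#' @return List with per-subject `rho`, `fisher_z`, and the group `z`,
#'   `p` from [wilcoxon_signed_rank()].
#' @export
corr_group_test <- function(x, y, subject) {
  stopifnot(length(x) == length(y), length(x) == length(subject))
  subs <- sort(unique(subject))
  rho <- vapply(subs, function(s) {
    i <- subject == s & !is.na(x) & !is.na(y)
    if (sum(i) < 5) stop("fewer than 5 trials for subject ", s)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0)
      stop("constant series for subject ", s)
    stats::cor(x[i], y[i], method = "spearman")
  }, numeric(1))
  fz <- atanh(pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12))
  gt <- wilcoxon_signed_rank(fz)
  list(rho = stats::setNames(rho, subs), fisher_z = fz,
       z = gt$z, p = gt$p)
}

#' Minimum sample size for a matched-pairs signed-rank test
#'
#' Design-stage power computation using the asymptotic-relative-efficiency
#' method: the signed-rank test on `n` pairs from a normal parent has the
#' power of a paired t-test on `n * 3 / pi` effective pairs, evaluated via
#' the noncentral t distribution.  Returns the smallest `n` reaching the
#' target power for a two-tailed test.
#'
#' @param dz effect size (mean difference / SD of differences).
#' @param alpha two-tailed significance level (default 0.05).
#' @param power target power (default 0.9).
#' @param n_max search bound.
#' @return Integer minimum sample size.
#' @export
wilcoxon_power_n <- function(dz, alpha = 0.05, power = 0.9, n_max = 10000) {
  stopifnot(dz > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  are <- 3 / pi
  pw <- function(n) {
    m <- n * are                  # effective sample size (may be fractional)
    df <- m - 1
    if (df <= 0) return(0)
    ncp <- dz * sqrt(m)
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
  }
  for (n in 3:n_max) if (pw(n) >= power) return(n)
  stop("target power unreachable within n_max")
}

#' Critical Z for multiple one-sided comparisons
#'
#' `qnorm(1 - alpha / n_tests)`: e.g. 2.24 for alpha 0.05 corrected over
#' 4 tests, 1.65 uncorrected.
#'
#' @param alpha significance level.
#' @param n_tests number of tests corrected for (default 1).
#' @return Critical Z value.
#' @export
z_threshold <- function(alpha = 0.05, n_tests = 1) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  stats::qnorm(1 - alpha / n_tests)
}
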