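#' Sliding window grid
#'
#' Time-window grid for stimulation labelling: 100 ms windows stepped by
#' 10 ms, spanning 0 to +1000 ms around the cue or -1000 to 0 ms around
#' the response.  Windows are half-open `[start, start + width)`.
#'
#' @param alignment `"cue"` or `"response"`.
#' @param width_ms window width in ms (default 100).
#' @param step_ms step between window starts in ms (default 10).
#' @param span_ms length-2 span in ms; defaults to `c(0, 1000)` for cue
#'   alignment and `c(-1000, 0)` for response alignment.
#' @return List of class `window_grid` with `starts_ms` (window starts).
#' @export
window_grid <- function(alignment = c("cue", "response"), width_ms = 100,
                        step_ms = 10, span_ms = NULL) {
  alignment <- match.arg(alignment)
  if (is.null(span_ms))
    span_ms <- if (alignment == "cue") c(0, 1000) else c(-1000, 0)
  starts <- seq(span_ms[1], span_ms[2] - width_ms, by = step_ms)
  structure(list(alignment = alignment, width_ms = width_ms,
                 step_ms = step_ms, span_ms = span_ms, starts_ms = starts),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("%s-aligned grid: %d windows of %g ms stepped by %g ms over [%g, %g] ms\n",
              x$alignment, length(x$starts_ms), x$width_ms, x$step_ms,
              x$span_ms[1], x$span_ms[2]))
  invisible(x)
}

# cumulative-sum helper: number of TRUE samples of `mask` in [i0, i1]
.mask_counts <- function(cmask, i0, i1) {
  cmask[pmin(i1, length(cmask) - 1L) + 1L] - cmask[pmax(i0, 1L)]
}

#' Per-trial, per-window stimulation labels
#'
#' Marks, for every trial and every window of the grid, whether any
#' effective-stimulation sample falls inside the window (irrespective of
#' stimulation duration).
#'
#' @param mask logical effective-stimulation mask over session samples.
#' @param events per-trial alignment samples (cue or response sample
#'   indices, 1-based); `NA` events yield `NA` labels.
#' @param fs sampling rate of the mask in Hz.
#' @param grid a [window_grid()].
#' @return Logical matrix, trials x windows.
#' @export
window_stim_labels <- function(mask, events, fs, grid) {
  stopifnot(inherits(grid, "window_grid"))
  mask <- as.logical(mask)
  ok <- !is.na(events)
  ev <- events[ok]
  lo <- min(ev) + round(grid$span_ms[1] / 1000 * fs)
  hi <- max(ev) + round((grid$span_ms[2]) / 1000 * fs)
  if (lo < 1 || hi > length(mask))
    stop("event windows extend outside the mask extent")
  cmask <- c(0L, cumsum(as.integer(mask)))
  out <- matrix(NA, length(events), length(grid$starts_ms))
  for (w in seq_along(grid$starts_ms)) {
    i0 <- ev + round(grid$starts_ms[w] / 1000 * fs)
    i1 <- i0 + round(grid$width_ms / 1000 * fs) - 1L
    out[ok, w] <- .mask_counts(cmask, i0, i1) > 0L
  }
  out
}

#' Mean percent time stimulation is ON per window
#'
#' Average over trials of the percentage of window samples with
#' (effective) stimulation ON.
#'
#' @inheritParams window_stim_labels
#' @return Numeric vector, one mean percentage per window.
#' @export
percent_time_on <- function(mask, events, fs, grid) {
  stopifnot(inherits(grid, "window_grid"))
  mask <- as.logical(mask)
  ok <- !is.na(events)
  ev <- events[ok]
  cmask <- c(0L, cumsum(as.integer(mask)))
  wn <- round(grid$width_ms / 1000 * fs)
  vapply(seq_along(grid$starts_ms), function(w) {
    i0 <- ev + round(grid$starts_ms[w] / 1000 * fs)
    i1 <- i0 + wn - 1L
    mean(.mask_counts(cmask, i0, i1) / wn) * 100
  }, numeric(1))
}

#' Per-patient, per-window stimulation-effect contrast
#'
#' For every patient and window, the double difference between the factor
#' effect in stimulated versus unstimulated trials, using median cell
#' summaries: for coherence,
#' `(RT_low_stim - RT_high_stim) - (RT_low_nostim - RT_high_nostim)`;
#' for instruction, `(RT_acc_stim - RT_speed_stim) - (RT_acc_nostim -
#' RT_speed_nostim)`.  Negative values mean reduced slowing (coherence) or
#' reduced instruction-related speeding under stimulation.  Windows where
#' any cell is empty yield `NA` for that patient.
#'
#' @param trials trial table with `patient`, `rt_s`, `omission`, and the
#'   factor column (`coherence` or `instruction`).
#' @param labels logical trials x windows label matrix
#'   ([window_stim_labels()]), rows matching `trials`.
#' @param factor `"coherence"` or `"instruction"`.
#' @param scale `"ms"` (difference of medians in ms) or `"percent"`
#'   (stimulated effect relative to unstimulated effect).
#' @return Numeric matrix patients x windows with the window grid attached
#'   as attribute `grid` when `labels` carries one.
#' @export
stim_contrast <- function(trials, labels, factor = c("coherence", "instruction"),
                          scale = c("ms", "percent")) {
  factor <- match.arg(factor)
  scale <- match.arg(scale)
  if (nrow(trials) != nrow(labels)) stop("trials/labels row mismatch")
  lv <- if (factor == "coherence") c("low", "high") else c("accuracy", "speed")
  keep <- !trials$omission & !is.na(trials$rt_s)
  patients <- sort(unique(trials$patient))
  nw <- ncol(labels)
  out <- matrix(NA_real_, length(patients), nw,
                dimnames = list(patient = patients, window = NULL))
  f <- trials[[factor]]
  for (pi in seq_along(patients)) {
    rows <- keep & trials$patient == patients[pi]
    rt <- trials$rt_s[rows]
    fv <- f[rows]
    lb <- labels[rows, , drop = FALSE]
    for (w in seq_len(nw)) {
      s <- lb[, w]
      if (any(is.na(s))) s[is.na(s)] <- FALSE
      cells <- c(stats::median(rt[fv == lv[1] & s]),
                 stats::median(rt[fv == lv[2] & s]),
                 stats::median(rt[fv == lv[1] & !s]),
                 stats::median(rt[fv == lv[2] & !s]))
      if (any(is.na(cells))) next
      eff_stim <- cells[1] - cells[2]
      eff_nostim <- cells[3] - cells[4]
      out[pi, w] <- if (scale == "ms") (eff_stim - eff_nostim) * 1000
                    else (eff_stim - eff_nostim) / eff_nostim * 100
    }
  }
  if (all(is.na(out)))
    stop("no window has all four cells populated; ",
         "stimulation labels carry no contrast (e.g. continuous stimulation)")
  out
}

#' Cluster-based permutation test on window effects
#'
#' Computes a per-window one-sample statistic across patients, thresholds
#' it, forms maximal contiguous supra-threshold clusters, and compares
#' each observed cluster statistic against the permutation distribution of
#' the maximum cluster statistic obtained by randomly flipping the
#' condition labels (stimulated vs unstimulated, i.e. the sign of each
#' patient's contrast).  A cluster is significant when its statistic
#' exceeds the 95th percentile of that null distribution.
#'
#' @param effects numeric matrix patients x windows (may contain `NA`).
#' @param z_thresh per-window threshold; the default 2.24 is
#'   `qnorm(1 - 0.05/4)`, correcting for four separate sliding-window
#'   tests.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutation draws.
#' @param stat per-window statistic: `"z"` (mean / (SD/sqrt(n)), the
#'   one-sample z the threshold is calibrated for) or `"mean_sd"`
#'   (mean / SD).
#' @param cluster_stat `"mass"` (sum of supra-threshold absolute
#'   statistics) or `"size"` (number of windows).
#' @param min_patients windows with fewer non-missing patients are
#'   excluded (default 4).
#' @return Tibble of clusters (`start`, `end` window indices, `mass`,
#'   `p_value`, `significant`) with the per-window statistics in attribute
#'   `z` and the permutation maxima in attribute `perm_max`.
#' @export
cluster_permutation <- function(effects, z_thresh = 2.24, n_perm = 1000,
                                seed = NULL, stat = c("z", "mean_sd"),
                                cluster_stat = c("mass", "size"),
                                min_patients = 4) {
  stat <- match.arg(stat)
  cluster_stat <- match.arg(cluster_stat)
  if (nrow(effects) < 2) stop("need at least 2 patients")
  if (!is.null(seed)) set.seed(seed)

  n_ok <- colSums(!is.na(effects))
  use <- n_ok >= min_patients
  zfun <- function(x) {
    m <- colMeans(x, na.rm = TRUE)
    s <- apply(x, 2, stats::sd, na.rm = TRUE)
    z <- if (stat == "z") m / (s / sqrt(colSums(!is.na(x)))) else m / s
    z[!use | s == 0] <- 0
    z
  }
  clusters_of <- function(z) {
    supra <- abs(z) >= z_thresh
    r <- rle(supra)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ix <- which(r$values)
    if (!length(ix)) return(NULL)
    data.frame(start = starts[ix], end = ends[ix],
               mass = vapply(ix, function(j) {
                 w <- starts[j]:ends[j]
                 if (cluster_stat == "mass") sum(abs(z[w])) else length(w)
               }, numeric(1)))
  }

  z_obs <- zfun(effects)
  obs <- clusters_of(z_obs)

  S <- nrow(effects)
  perm_max <- vapply(seq_len(n_perm), function(i) {
    flip <- sample(c(-1, 1), S, replace = TRUE)
    cl <- clusters_of(zfun(effects * flip))
    if (is.null(cl)) 0 else max(cl$mass)
  }, numeric(1))

  crit <- stats::quantile(perm_max, 0.95, names = FALSE)
  if (is.null(obs)) {
    out <- tibble::tibble(start = integer(), end = integer(),
                          mass = numeric(), p_value = numeric(),
                          significant = logical())
  } else {
    out <- tibble::tibble(
      start = obs$start, end = obs$end, mass = obs$mass,
      p_value = vapply(obs$mass,
                       function(m) (1 + sum(perm_max >= m)) / (n_perm + 1),
                       numeric(1)),
      significant = obs$mass > crit
    )
  }
  attr(out, "z") <- z_obs
  attr(out, "perm_max") <- perm_max
  attr(out, "critical") <- crit
  out
}
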