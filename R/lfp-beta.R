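#' Select the recording contact with the strongest beta peak
#'
#' Given per-channel power spectra (1 Hz resolution), selects the channel
#' whose beta-band (default 13-30 Hz) peak power is largest.  A peak is a
#' local maximum within the band; channels without one are not eligible.
#' Ties go to the lower channel index (flagged); if no channel has a beta
#' peak the first channel is returned with `no_peak = TRUE`.
#'
#' @param spectra numeric matrix, frequencies x channels.
#' @param freqs frequency axis in Hz (rows of `spectra`).
#' @param beta_band length-2 band limits in Hz.
#' @return List with `channel`, `peak_hz`, `tie`, `no_peak`.
#' @export
select_contact <- function(spectra, freqs, beta_band = c(13, 30)) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) < 2) stop("need at least 2 candidate channels")
  stopifnot(nrow(spectra) == length(freqs))
  in_band <- freqs >= beta_band[1] & freqs <= beta_band[2]
  peak <- rep(NA_real_, ncol(spectra))
  peak_f <- rep(NA_real_, ncol(spectra))
  for (ch in seq_len(ncol(spectra))) {
    p <- spectra[, ch]
    # local maxima strictly above both neighbours
    loc <- which(diff(sign(diff(p))) == -2) + 1L
    loc <- loc[in_band[loc]]
    if (length(loc)) {
      j <- loc[which.max(p[loc])]
      peak[ch] <- p[j]; peak_f[ch] <- freqs[j]
    }
  }
  if (all(is.na(peak)))
    return(list(channel = 1L, peak_hz = NA_real_, tie = FALSE, no_peak = TRUE))
  best <- max(peak, na.rm = TRUE)
  hits <- which(!is.na(peak) & peak == best)
  list(channel = hits[1], peak_hz = peak_f[hits[1]],
       tie = length(hits) > 1, no_peak = FALSE)
}

#' Preprocess an LFP series for time-frequency analysis
#'
#' Anti-aliased down-sampling to 200 Hz followed by a zero-phase 1 Hz
#' high-pass (2nd-order Butterworth, forward-backward).
#'
#' @param lfp numeric vector.
#' @param fs_in input sampling rate in Hz; must be at least 200.
#' @param fs_out output rate (default 200).
#' @param hp_hz high-pass corner (default 1).
#' @return List with `values` and `fs`.
#' @export
preprocess_lfp <- function(lfp, fs_in, fs_out = 200, hp_hz = 1) {
  if (fs_in < fs_out) stop("`fs_in` must be at least ", fs_out, " Hz")
  x <- as.numeric(lfp)
  if (fs_in > fs_out) {
    aa <- signal::butter(4, 0.8 * (fs_out / 2) / (fs_in / 2), type = "low")
    x <- signal::filtfilt(aa, x)
    t_in <- (seq_along(x) - 1) / fs_in
    t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
    x <- stats::approx(t_in, x, xout = t_out)$y
  }
  hp <- signal::butter(2, hp_hz / (fs_out / 2), type = "high")
  list(values = signal::filtfilt(hp, x), fs = fs_out)
}

#' Morlet wavelet time-frequency power
#'
#' Continuous wavelet transform at 3-30 Hz in 1 Hz steps with the linear
#' cycle rule `cycles(f) = 2 + 3 (f - 3) / 27` (2 cycles at 3 Hz rising to
#' 5 at 30 Hz).  The wavelet is amplitude-normalized so a unit-amplitude
#' sinusoid yields unit amplitude (power 1) at its frequency.  Samples
#' within one wavelet half-length of either edge are flagged invalid.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param freqs analysis frequencies (default `3:30`).
#' @return Object of class `tf_power`: list with `power` (time x
#'   frequency), `valid` (logical matrix), `freqs`, `fs`.
#' @export
wavelet_power <- function(x, fs, freqs = 3:30) {
  n <- length(x)
  cycles <- 2 + 3 * (freqs - 3) / 27
  sigma_t <- cycles / (2 * pi * freqs)
  half_len <- ceiling(3 * sigma_t * fs)
  if (n <= 2 * max(half_len)) stop("series shorter than the longest wavelet")
  nfft <- stats::nextn(n + 2 * max(half_len), 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  power <- matrix(NA_real_, n, length(freqs))
  valid <- matrix(TRUE, n, length(freqs))
  for (j in seq_along(freqs)) {
    hl <- half_len[j]
    tt <- (-hl:hl) / fs
    w <- exp(2i * pi * freqs[j] * tt) * exp(-tt^2 / (2 * sigma_t[j]^2))
    w <- 2 * w / sum(abs(w))      # amplitude-preserving normalization
    W <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::fft(X * W, inverse = TRUE) / nfft
    amp <- Mod(conv[(hl + 1):(hl + n)])
    power[, j] <- amp^2
    valid[c(seq_len(min(hl, n)), seq.int(max(1L, n - hl + 1L), n)), j] <- FALSE
  }
  structure(list(power = power, valid = valid, freqs = freqs, fs = fs),
            class = "tf_power")
}

#' Normalize time-frequency power per frequency
#'
#' Divides each frequency's power by its mean over the whole experiment
#' (valid samples only), so normalized power has experiment-wide mean 1 at
#' every frequency.
#'
#' @param tf a [wavelet_power()] object.
#' @return The object with normalized `power` and `norm` (per-frequency
#'   means used).
#' @export
normalize_tf <- function(tf) {
  stopifnot(inherits(tf, "tf_power"))
  norm <- vapply(seq_along(tf$freqs), function(j)
    mean(tf$power[tf$valid[, j], j]), numeric(1))
  tf$power <- sweep(tf$power, 2, norm, "/")
  tf$norm <- norm
  tf
}

#' Cue-locked single-trial beta traces
#'
#' Extracts per-trial beta-power traces (mean over a frequency band, or a
#' single frequency) aligned to trial events.
#'
#' @param tf a (normalized) [wavelet_power()] object for the session.
#' @param events event sample indices (1-based), `NA` allowed.
#' @param win length-2 window in seconds around the event (default
#'   `c(-0.1, 1.5)`).
#' @param band frequency band to average over (default 13-30 Hz); a single
#'   frequency may be given as `c(f, f)`.
#' @return List with `traces` (time x trials), `time_s`.
#' @export
epoch_beta <- function(tf, events, win = c(-0.1, 1.5), band = c(13, 30)) {
  stopifnot(inherits(tf, "tf_power"))
  sel <- tf$freqs >= band[1] & tf$freqs <= band[2]
  beta <- rowMeans(tf$power[, sel, drop = FALSE])
  i0 <- round(win[1] * tf$fs); i1 <- round(win[2] * tf$fs)
  idx <- i0:i1
  traces <- vapply(events, function(e) {
    if (is.na(e)) return(rep(NA_real_, length(idx)))
    ii <- e + idx
    out <- rep(NA_real_, length(idx))
    ok <- ii >= 1 & ii <= length(beta)
    out[ok] <- beta[ii[ok]]
    out
  }, numeric(length(idx)))
  list(traces = traces, time_s = idx / tf$fs)
}

#' Response-capped condition average
#'
#' Averages single-trial power traces after capping each trial at its
#' response time; the average is reported from the start of the traces
#' until the time point at which 50% of the condition's trials still
#' contribute (the condition's median RT).
#'
#' @param traces matrix time x trials (cue-locked, starting at
#'   `time_s[1]`).
#' @param time_s time axis in seconds relative to the cue.
#' @param rts per-trial RTs in seconds (`NA` = never capped).
#' @return List with `mean` (capped average, `NA` beyond the valid
#'   extent), `valid_until_s`.
#' @export
capped_average <- function(traces, time_s, rts) {
  if (ncol(traces) == 0) stop("empty condition")
  capped <- traces
  for (k in seq_len(ncol(traces)))
    if (!is.na(rts[k])) capped[time_s > rts[k] + 1e-9, k] <- NA
  contrib <- rowSums(!is.na(capped))
  valid <- contrib >= ceiling(ncol(traces) / 2)
  m <- rowMeans(capped, na.rm = TRUE)
  m[!valid] <- NA
  list(mean = m, valid_until_s = if (any(valid)) max(time_s[valid]) else NA)
}

#' Cue-induced beta decrease per trial
#'
#' Difference between beta power 100-150 ms post-cue (the post-cue
#' maximum) and power around the subject's beta trough, with the trough
#' latency estimated once per subject from the average trace within
#' 300-500 ms and applied to every trial (+/- `trough_halfwidth_s`).
#' Values are z-scored within subject for regression use.
#'
#' @param traces matrix time x trials of cue-locked beta power.
#' @param time_s time axis in seconds relative to the cue.
#' @param trough_search window for the subject trough (default
#'   `c(0.3, 0.5)` s).
#' @param trough_halfwidth_s half width around the trough (default 0.1).
#' @param zscore z-score within subject (default TRUE).
#' @return Numeric per-trial vector (attribute `trough_s` is the subject
#'   trough latency).
#' @export
cue_beta_decrease <- function(traces, time_s, trough_search = c(0.3, 0.5),
                              trough_halfwidth_s = 0.1, zscore = TRUE) {
  if (max(time_s) < 0.5)
    stop("traces must extend at least 500 ms post-cue")
  avg <- rowMeans(traces, na.rm = TRUE)
  sw <- time_s >= trough_search[1] & time_s <= trough_search[2]
  trough_s <- time_s[sw][which.min(avg[sw])]
  early <- time_s >= 0.10 & time_s <= 0.15
  tw <- time_s >= trough_s - trough_halfwidth_s &
        time_s <= trough_s + trough_halfwidth_s
  val <- colMeans(traces[early, , drop = FALSE], na.rm = TRUE) -
         colMeans(traces[tw, , drop = FALSE], na.rm = TRUE)
  if (zscore) val <- as.numeric(scale(val))
  attr(val, "trough_s") <- trough_s
  val
}

#' Late beta power per trial, split by coherence
#'
#' Mean normalized beta power in the 500-800 ms post-cue window, z-scored
#' within subject separately for low- and high-coherence trials, emitted
#' as the `beta_lc_z` / `beta_hc_z` regressor columns (zero outside the
#' respective coherence).
#'
#' Because beta power decreases during the motor response, trials whose
#' response falls inside the analysis window couple the regressor to RT,
#' and any RT-dependent regressor (or RT-dependent trial exclusion)
#' biases a trial-wise threshold regression.  Two optional guards are
#' provided: `detrend_rt` partials a smooth RT trend out of the metric
#' within subject and coherence before z-scoring, and `exclude_short`
#' zeroes the regressor for trials with `rt < window[2]` (mirroring the
#' robustness analysis of excluding fast trials, without truncating the
#' likelihood).
#'
#' @param traces matrix time x trials of cue-locked beta power.
#' @param time_s time axis in seconds.
#' @param coherence per-trial `"low"`/`"high"`.
#' @param rts per-trial RT in seconds (`NA` = no response).
#' @param window analysis window (default `c(0.5, 0.8)` s).
#' @param detrend_rt partial out a smooth RT trend before z-scoring
#'   (default FALSE).
#' @param exclude_short zero the regressor for trials with `rt <
#'   min_rt` (default FALSE).
#' @param min_rt RT cutoff used by `exclude_short`, in seconds; defaults
#'   to the window end.
#' @return Tibble with `beta_late` (raw window mean), `beta_lc_z`,
#'   `beta_hc_z`, `keep`.
#' @export
late_beta <- function(traces, time_s, coherence, rts,
                      window = c(0.5, 0.8), detrend_rt = FALSE,
                      exclude_short = FALSE, min_rt = window[2]) {
  if (max(time_s) < window[2])
    stop("traces do not cover the late window")
  n <- ncol(traces)
  ww <- time_s >= window[1] & time_s <= window[2]
  val <- colMeans(traces[ww, , drop = FALSE], na.rm = TRUE)
  keep <- !is.na(val)
  if (exclude_short) keep <- keep & !is.na(rts) & rts >= min_rt
  zsub <- function(v) if (sum(!is.na(v)) > 1) as.numeric(scale(v)) else v * 0
  score <- function(group) {
    i <- group & keep
    out <- rep(0, n)
    if (sum(i) < 8) return(out)
    v <- val[i]
    if (detrend_rt) {
      r <- rts[i]
      r[is.na(r)] <- max(r, na.rm = TRUE)
      v <- stats::resid(stats::lm(v ~ stats::poly(r, 3)))
    }
    out[i] <- zsub(v)
    out
  }
  low <- coherence == "low"
  lc <- score(low)
  hc <- score(!low)
  tibble::tibble(beta_late = val, beta_lc_z = lc, beta_hc_z = hc, keep = keep)
}

#' Append single-trial beta covariates to a session's trial table
#'
#' Runs the full chain on the session's synthetic raw LFP: wavelet power,
#' per-frequency normalization, cue-locked epoching at the beta band,
#' cue-induced decrease and late beta metrics; appends `beta_decrease_z`,
#' `beta_lc_z`, `beta_hc_z` (and `beta_keep`) to the trial table.
#'
#' @param session an `adbs_session` from [generate_session()].
#' @param exclude_short passed to [late_beta()].
#' @param use_envelope if TRUE skip the wavelet chain and use the
#'   generator's envelope directly (faster; for exploration).
#' @return The session's trial tibble with covariate columns appended.
#' @export
add_beta_covariates <- function(session, exclude_short = FALSE,
                                use_envelope = FALSE, ...) {
  stopifnot(inherits(session, "adbs_session"))
  env <- session$envelope
  if (use_envelope) {
    beta <- env$values^2
    fs <- env$fs
    ep <- local({
      i0 <- round(-0.1 * fs); i1 <- round(1.5 * fs)
      idx <- i0:i1
      traces <- vapply(env$cue_samples, function(e) beta[e + idx],
                       numeric(length(idx)))
      list(traces = traces, time_s = idx / fs)
    })
  } else {
    tf <- normalize_tf(wavelet_power(env$lfp, env$fs))
    ep <- epoch_beta(tf, env$cue_samples)
  }
  trials <- session$trials
  dec <- cue_beta_decrease(ep$traces, ep$time_s)
  lb <- late_beta(ep$traces, ep$time_s, trials$coherence, trials$rt_s,
                  exclude_short = exclude_short, ...)
  trials$beta_decrease_z <- as.numeric(dec)
  trials$beta_late <- lb$beta_late
  trials$beta_lc_z <- lb$beta_lc_z
  trials$beta_hc_z <- lb$beta_hc_z
  trials$beta_keep <- lb$keep
  trials
}
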