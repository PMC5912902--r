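#' Beta-amplitude envelope from a band-limited signal
#'
#' Emulates the on-device feedback chain: the signal is band-pass filtered
#' around the beta peak, rectified, and smoothed with a causal moving
#' average (default 400 ms).  The band must lie within the 3-37 Hz analog
#' passband of the recording chain.
#'
#' @param lfp numeric vector, band-limited LFP (or broadband at `fs`).
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, band edges in Hz within `[3, 37]`.
#' @param smooth_ms causal moving-average length in ms (default 400).
#' @return An object of class `beta_envelope`: list with `values`, `fs`,
#'   and empty event markers.
#' @export
beta_envelope <- function(lfp, fs, band = c(13, 30), smooth_ms = 400) {
  stopifnot(is.numeric(lfp), fs > 0, length(band) == 2)
  if (band[1] < 3 || band[2] > 37 || band[1] >= band[2])
    stop("`band` must lie within the 3-37 Hz passband")
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, lfp)
  smooth_causal(abs(filt), fs, smooth_ms, env = TRUE)
}

# causal moving average (O(n) via cumulative sums; the warm-up head uses
# growing partial windows); returns a beta_envelope when env = TRUE
smooth_causal <- function(x, fs, smooth_ms, env = FALSE) {
  k <- max(1L, round(smooth_ms / 1000 * fs))
  n <- length(x)
  cs <- cumsum(x)
  sm <- numeric(n)
  head_n <- min(k, n)
  sm[seq_len(head_n)] <- cs[seq_len(head_n)] / seq_len(head_n)
  if (n > k) {
    i <- (k + 1L):n
    sm[i] <- (cs[i] - cs[i - k]) / k
  }
  if (!env) return(sm)
  new_beta_envelope(sm, fs)
}

new_beta_envelope <- function(values, fs, cue_samples = integer(),
                              resp_samples = integer()) {
  structure(list(values = values, fs = fs,
                 cue_samples = cue_samples, resp_samples = resp_samples),
            class = "beta_envelope")
}

#' @export
print.beta_envelope <- function(x, ...) {
  cat("Beta envelope:", length(x$values), "samples at", x$fs, "Hz,",
      length(x$cue_samples), "cue markers\n")
  invisible(x)
}

#' Run the closed-loop amplitude trigger
#'
#' Simulates the beta-triggered controller: the trigger turns ON whenever
#' the envelope is at or above `threshold` (outside the lockout period) and
#' OFF as soon as it falls below.  Stimulation voltage ramps linearly up
#' and down over `ramp_ms`; a lockout period of `lockout_ms` starting at
#' each trigger-off signal blocks re-triggering.
#'
#' @param env a [beta_envelope()] object or numeric vector.
#' @param threshold trigger threshold on the envelope scale (> 0);
#'   typically the envelope median.
#' @param ramp_ms voltage ramp duration in ms (default 250).
#' @param lockout_ms lockout after trigger-off in ms (default 500).
#' @param fs sampling rate, required when `env` is a bare vector.
#' @return An object of class `stim_trace`: list with `fs`,
#'   `trigger_state` (0/1), `voltage_fraction` in `[0, 1]`, and
#'   `effective_mask` (TRUE only at full voltage).
#' @export
run_trigger <- function(env, threshold, ramp_ms = 250, lockout_ms = 500,
                        fs = NULL) {
  if (inherits(env, "beta_envelope")) {
    fs <- env$fs
    values <- env$values
  } else {
    if (is.null(fs)) stop("`fs` required when `env` is a plain vector")
    values <- as.numeric(env)
  }
  if (!is.finite(threshold) || threshold <= 0)
    stop("`threshold` must be positive")
  out <- adbs_trigger_cpp(values, fs, threshold, ramp_ms, lockout_ms)
  new_stim_trace(fs, out$trigger, out$voltage)
}

new_stim_trace <- function(fs, trigger, voltage) {
  structure(list(fs = fs,
                 trigger_state = as.integer(trigger),
                 voltage_fraction = as.numeric(voltage),
                 effective_mask = as.numeric(voltage) >= 1 - 1e-9),
            class = "stim_trace")
}

#' @export
print.stim_trace <- function(x, ...) {
  cat(sprintf("Stim trace: %d samples at %g Hz, trigger duty %.1f%%, effective duty %.1f%%\n",
              length(x$trigger_state), x$fs,
              100 * mean(x$trigger_state), 100 * mean(x$effective_mask)))
  invisible(x)
}

#' Clinically effective stimulation mask
#'
#' Stimulation counts as ON only at the clinically effective voltage, i.e.
#' when the voltage fraction has completed its ramp; the ramp-up time is
#' treated as stimulation OFF.
#'
#' @param trace a `stim_trace` from [run_trigger()].
#' @return Logical vector, TRUE where stimulation is at full voltage.
#' @export
effective_stim_mask <- function(trace) {
  stopifnot(inherits(trace, "stim_trace"))
  trace$effective_mask
}

#' Surrogate stimulation mask from an off-stimulation envelope
#'
#' Reconstructs when stimulation would have been triggered from an
#' envelope recorded without stimulation: the surrogate trigger is ON
#' whenever the envelope exceeds the `1 - duty_target` quantile, and the
#' first 250 ms (the ramp time) of every ON episode are removed.  The
#' per-patient `duty_target` should equal that patient's realized trigger
#' duty during closed-loop stimulation.
#'
#' @param env_off a [beta_envelope()] (or numeric vector with `fs`).
#' @param duty_target target trigger duty in (0, 1).
#' @param ramp_ms ramp time removed from each episode onset (default 250).
#' @param fs sampling rate when `env_off` is a bare vector.
#' @return Logical surrogate-stimulation mask.
#' @export
surrogate_stim <- function(env_off, duty_target, ramp_ms = 250, fs = NULL) {
  if (inherits(env_off, "beta_envelope")) {
    fs <- env_off$fs; values <- env_off$values
  } else {
    if (is.null(fs)) stop("`fs` required when `env_off` is a plain vector")
    values <- as.numeric(env_off)
  }
  if (duty_target <= 0 || duty_target >= 1)
    stop("`duty_target` must lie in (0, 1)")
  thr <- stats::quantile(values, 1 - duty_target, names = FALSE)
  on <- values >= thr
  ramp_n <- round(ramp_ms / 1000 * fs)
  # remove the first ramp_n samples of each ON episode
  out <- on
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    e <- min(ends[j], starts[j] + ramp_n - 1L)
    out[starts[j]:e] <- FALSE
  }
  out
}
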