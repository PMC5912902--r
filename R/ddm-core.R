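#' Drift-diffusion model parameters
#'
#' Bundle of the three estimated parameters of the drift-diffusion model
#' (DDM) used throughout the package, with the two fixed conventions: the
#' relative start point `z = 0.5` (both responses equally likely a priori)
#' and diffusion scale `s = 1` (all coefficients are reported in that
#' scale convention).
#'
#' @param v drift rate (evidence units per second).
#' @param a boundary separation (evidence units); must be positive.
#' @param t non-decision time in seconds; must be non-negative.
#' @param z relative start point, fixed at 0.5.
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(v, a, t, z = 0.5) {
  stopifnot(is.numeric(v), is.numeric(a), is.numeric(t))
  if (any(a <= 0)) stop("boundary separation `a` must be positive")
  if (any(t < 0)) stop("non-decision time `t` must be non-negative")
  if (any(z <= 0 | z >= 1)) stop("start point `z` must lie in (0, 1)")
  structure(list(v = v, a = a, t = t, z = z), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("DDM parameters: v =", x$v, " a =", x$a, " t =", x$t,
      " (z =", x$z, ", s = 1)\n")
  invisible(x)
}

#' Wiener first-passage-time density
#'
#' Density of the response time at the upper or lower boundary of a
#' drift-diffusion process, computed with an adaptive switch between the
#' small-time and large-time series expansions so the truncation error is
#' below `tol`.
#'
#' @param rt response times in seconds (including non-decision time).
#' @param boundary `"upper"` or `"lower"`; recycled over `rt`.
#' @param params a [ddm_params()] object (scalar parameters).
#' @param tol series truncation tolerance (default `1e-7`).
#' @return Numeric vector of densities; zero for `rt <= t`.
#' @examples
#' p <- ddm_params(v = 1, a = 2, t = 0.3)
#' wfpt_density(seq(0.4, 2, by = 0.4), "upper", p)
#' @export
wfpt_density <- function(rt, boundary = c("upper", "lower"), params,
                         tol = 1e-7) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "ddm_params"), tol > 0)
  if (any(!is.finite(rt))) stop("`rt` must be finite")
  n <- length(rt)
  wfpt_pdf_cpp(rt, rep.int(as.integer(boundary == "upper"), n),
               rep.int(params$a, n), rep.int(params$v, n),
               rep.int(params$t, n), params$z, tol)
}

#' Simulate drift-diffusion trials
#'
#' Forward Euler-Maruyama simulation of the DDM (diffusion scale 1).
#' Trials that do not terminate before `t_max` seconds of accumulation are
#' returned with `NA` response time.
#'
#' @param params a [ddm_params()] object; elements may be scalars or
#'   length-`n` vectors for trial-wise parameters.
#' @param n number of trials.
#' @param dt Euler step in seconds (default `1e-4`).
#' @param seed optional integer seed.
#' @param t_max maximum accumulation time before a trial is abandoned.
#' @return A [tibble::tibble()] with columns `rt` (seconds) and `boundary`
#'   (`"upper"`/`"lower"`).
#' @export
simulate_ddm <- function(params, n, dt = 1e-4, seed = NULL, t_max = 20) {
  stopifnot(inherits(params, "ddm_params"))
  if (n <= 0) stop("`n` must be positive")
  if (!is.null(seed)) set.seed(seed)
  a <- rep_len(params$a, n); v <- rep_len(params$v, n)
  t0 <- rep_len(params$t, n)
  sim <- ddm_simulate_cpp(a, v, t0, params$z, dt, t_max)
  tibble::tibble(
    rt = sim$rt,
    boundary = ifelse(is.na(sim$upper), NA_character_,
                      ifelse(sim$upper == 1L, "upper", "lower"))
  )
}

#' Closed-form absorption probability at the upper boundary
#'
#' For drift `v`, separation `a`, start point `z` and unit diffusion, the
#' probability of absorbing at the upper boundary is
#' `(1 - exp(-2 v a z)) / (1 - exp(-2 v a))`, reducing to `z` at `v = 0`.
#' Used as an analytic cross-check of the density and the simulator.
#'
#' @inheritParams simulate_ddm
#' @return Probability of an upper-boundary response.
#' @export
ddm_p_upper <- function(params) {
  v <- params$v; a <- params$a; z <- params$z
  ifelse(abs(v) < 1e-10, z, (1 - exp(-2 * v * a * z)) / (1 - exp(-2 * v * a)))
}

#' Closed-form mean decision time for a symmetric start point
#'
#' With `z = 0.5` the mean first-passage time (over both boundaries,
#' excluding non-decision time) is `(a / (2 v)) * tanh(v a / 2)`; the
#' zero-drift limit is `a^2 / 4`.
#'
#' @inheritParams simulate_ddm
#' @return Mean decision time in seconds.
#' @export
ddm_mean_dt <- function(params) {
  if (params$z != 0.5) stop("closed form requires z = 0.5")
  v <- params$v; a <- params$a
  ifelse(abs(v) < 1e-10, a^2 / 4, (a / (2 * v)) * tanh(v * a / 2))
}
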