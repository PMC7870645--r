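#' Wiener diffusion parameter set
#'
#' Bundles the parameters of the two-boundary drift-diffusion process. The
#' package uses the symmetric-boundary convention of the mean-behavior
#' closed forms: `boundary_separation` (a) is the evidence distance from the
#' unbiased starting point to each boundary, so the full span between the
#' absorbing boundaries is 2a. `rel_start` (z) is the relative starting
#' position within that span (0.5 = unbiased; values above 0.5 favor the
#' upper boundary, which is mapped to the RIGHT response throughout the
#' package).
#'
#' @param drift evidence accumulation rate toward the upper boundary
#'   (evidence units per second).
#' @param boundary_separation threshold distance a (> 0).
#' @param rel_start relative starting point z in (0, 1).
#' @param nondecision_time non-decision time T_er in seconds (>= 0).
#' @param diffusion_noise diffusion coefficient sigma (> 0); fixed at 1 by
#'   convention to set the evidence scale.
#' @return object of class `wiener_params`.
#' @export
wiener_params <- function(drift, boundary_separation, rel_start = 0.5,
                          nondecision_time = 0, diffusion_noise = 1) {
  stopifnot(is.numeric(drift), length(drift) == 1L, is.finite(drift))
  if (boundary_separation <= 0) stop("boundary_separation must be positive")
  if (rel_start <= 0 || rel_start >= 1) stop("rel_start must lie in (0, 1)")
  if (nondecision_time < 0) stop("nondecision_time must be nonnegative")
  if (diffusion_noise <= 0) stop("diffusion_noise must be positive")
  structure(list(drift = drift, boundary_separation = boundary_separation,
                 rel_start = rel_start, nondecision_time = nondecision_time,
                 diffusion_noise = diffusion_noise),
            class = "wiener_params")
}

#' Asymptotic choice probability of the unbiased diffusion
#'
#' Probability that the diffusion with drift `drift`, threshold `a` and
#' noise `sigma` (unbiased start) is absorbed at the upper boundary:
#' `1 - 1 / (1 + exp(2 * drift * a / sigma^2))`.
#'
#' @param drift drift rate (may be a vector).
#' @param boundary_separation threshold a (> 0).
#' @param diffusion_noise noise sigma (> 0).
#' @return probability of the upper-boundary (right) response.
#' @export
choice_probability <- function(drift, boundary_separation, diffusion_noise = 1) {
  if (boundary_separation <= 0) stop("boundary_separation must be positive")
  if (diffusion_noise <= 0) stop("diffusion_noise must be positive")
  plogis(2 * drift * boundary_separation / diffusion_noise^2)
}

#' Expected response time of the unbiased diffusion
#'
#' Mean RT `T_er + (a / drift) * tanh(drift * a / sigma^2)`, with the
#' analytic zero-drift limit `T_er + a^2 / sigma^2`.
#'
#' @inheritParams choice_probability
#' @param nondecision_time T_er in seconds.
#' @return expected response time in seconds.
#' @export
mean_rt <- function(drift, boundary_separation, diffusion_noise = 1,
                    nondecision_time = 0) {
  if (boundary_separation <= 0) stop("boundary_separation must be positive")
  if (diffusion_noise <= 0) stop("diffusion_noise must be positive")
  a <- boundary_separation
  s2 <- diffusion_noise^2
  dt <- ifelse(drift == 0, a^2 / s2, (a / drift) * tanh(drift * a / s2))
  nondecision_time + dt
}

#' Log first-passage-time density of the diffusion
#'
#' Log of the defective density of absorption at the indicated boundary at
#' time `rt`. The pair of densities (upper + lower) integrates to one over
#' `(T_er, Inf)`. Evaluation uses the series expansion of the Wiener
#' first-passage density with automatic small-time/large-time switching.
#'
#' @param rt response time(s) in seconds (> 0).
#' @param hit_upper logical (scalar or vector): TRUE for the upper/right
#'   boundary.
#' @param params a [wiener_params()] object.
#' @param drift optional per-observation drift vector overriding
#'   `params$drift` (used for trial-varying drifts).
#' @return log density; `-Inf` for `rt <= nondecision_time`.
#' @export
fpt_log_density <- function(rt, hit_upper, params, drift = NULL) {
  stopifnot(inherits(params, "wiener_params"))
  if (any(rt <= 0)) stop("rt must be positive")
  n <- length(rt)
  hit_upper <- rep_len(as.logical(hit_upper), n)
  v <- if (is.null(drift)) params$drift else drift
  out <- wfpt_logdens_cpp(as.numeric(rt), hit_upper,
                          2 * params$boundary_separation, params$rel_start,
                          params$nondecision_time, as.numeric(v),
                          params$diffusion_noise)
  if (any(is.nan(out))) stop("density evaluation produced NaN")
  out
}

#' Simulate diffusion trials by the Euler-Maruyama scheme
#'
#' Forward-simulates the two-boundary diffusion from `rel_start * 2a` with
#' increments `drift * dt + sigma * sqrt(dt) * N(0,1)` until a boundary is
#' hit or `max_time` is exceeded. Boundaries are shrunk inward by
#' `0.5826 * sigma * sqrt(dt)` to correct the first-order discretization
#' bias of discrete-time first passages. Trials that time out carry
#' `response = NA` (treated downstream as omitted responses). Reproducible
#' under `set.seed()`.
#'
#' @param params a [wiener_params()] object (its `drift` is used unless
#'   `drift` is given).
#' @param n number of trials (ignored when `drift` is a vector).
#' @param drift optional vector of per-trial drifts.
#' @param time_step Euler step in seconds.
#' @param max_time maximum total response time in seconds.
#' @param bias_correct apply the boundary continuity correction.
#' @return data.frame with columns `hit_upper` (logical, NA on timeout) and
#'   `rt` (seconds, NA on timeout).
#' @export
simulate_trials <- function(params, n = 1L, drift = NULL, time_step = 1e-3,
                            max_time = 10, bias_correct = TRUE) {
  stopifnot(inherits(params, "wiener_params"))
  v <- if (is.null(drift)) rep(params$drift, n) else as.numeric(drift)
  sim <- sim_ddm_cpp(v, 2 * params$boundary_separation, params$rel_start,
                     params$nondecision_time, params$diffusion_noise,
                     time_step, max_time, bias_correct)
  data.frame(hit_upper = ifelse(sim$response < 0, NA, sim$response == 1L),
             rt = sim$rt)
}
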