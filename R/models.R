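# Behavioral models: SPDM (single-process, biased reference value) and
# DPDM (dual-process utility/heuristic mixture). Trials are rows of a
# data.frame with columns participant, v_left, v_right (participant-mean-
# centered subjective values), rem_left, rem_right (0/1 remembered flags),
# response ("left"/"right"/"none") and rt_s (seconds). The analysis trials
# are "mixed" trials in which exactly one option is remembered; positive
# drift favors the right/upper boundary.

#' Subject-level SPDM parameters
#'
#' @param a threshold distance (> 0, evidence units).
#' @param z relative starting point in (0, 1); above 0.5 = right-side bias.
#' @param t_er non-decision time in seconds (> 0).
#' @param d_spdm drift scaling (> 0, drift per value unit).
#' @param gamma reference value against which the remembered option's value
#'   is compared (value units); `gamma` below the average value produces
#'   the memory bias.
#' @return object of class `spdm_params`.
#' @export
spdm_params <- function(a, z, t_er, d_spdm, gamma) {
  stopifnot(a > 0, z > 0, z < 1, t_er > 0, d_spdm > 0, is.finite(gamma))
  structure(list(a = a, z = z, t_er = t_er, d_spdm = d_spdm, gamma = gamma),
            class = "spdm_params")
}

#' Subject-level DPDM parameters
#'
#' @inheritParams spdm_params
#' @param d_utility drift scaling of the utility process (> 0).
#' @param d_heuristic drift magnitude of the value-blind heuristic process
#'   (> 0), always directed at the remembered option.
#' @param delta probability that a trial is governed by the utility process.
#'   The open interval (0, 1) is the estimable range; the closed boundaries
#'   are admitted for evaluating the degenerate single-component limits.
#' @param v_avg utility-process reference value; 0 for mean-centered values.
#' @return object of class `dpdm_params`.
#' @export
dpdm_params <- function(a, z, t_er, d_utility, d_heuristic, delta, v_avg = 0) {
  stopifnot(a > 0, z > 0, z < 1, t_er > 0, d_utility > 0, d_heuristic > 0,
            delta >= 0, delta <= 1, is.finite(v_avg))
  structure(list(a = a, z = z, t_er = t_er, d_utility = d_utility,
                 d_heuristic = d_heuristic, delta = delta, v_avg = v_avg),
            class = "dpdm_params")
}

# raw-scale parameter names per model (order matters: matches the sampler)
.par_names <- function(model_tag) {
  switch(model_tag,
         spdm = c("a", "z", "t_er", "d_spdm", "gamma"),
         dpdm = c("a", "z", "t_er", "d_utility", "d_heuristic", "delta"),
         stop("unknown model tag: ", model_tag))
}

.par_transforms <- function(model_tag) {
  switch(model_tag,
         spdm = c(a = "exp", z = "probit", t_er = "exp", d_spdm = "exp",
                  gamma = "identity"),
         dpdm = c(a = "exp", z = "probit", t_er = "exp", d_utility = "exp",
                  d_heuristic = "exp", delta = "probit"),
         stop("unknown model tag: ", model_tag))
}

.apply_transform <- function(x, how) {
  switch(how, exp = exp(x), probit = pnorm(x), identity = x,
         stop("unknown transform: ", how))
}

#' Map unconstrained draws to subject-level parameters
#'
#' Positive parameters (a, T_er, drift scalings) are exponentiated;
#' interval parameters (z, delta) go through the standard-normal CDF; the
#' reference value gamma is untouched. This is the transformation under
#' which the group-level normals live.
#'
#' @param raw_draw named (or positionally ordered) numeric vector of
#'   unconstrained values: `a, z, t_er, d_spdm, gamma` for `"spdm"`;
#'   `a, z, t_er, d_utility, d_heuristic, delta` for `"dpdm"`.
#' @param model_tag `"spdm"` or `"dpdm"`.
#' @param v_avg utility reference value attached to DPDM parameter sets.
#' @return an [spdm_params()] or [dpdm_params()] object.
#' @export
transform_subject_draw <- function(raw_draw, model_tag, v_avg = 0) {
  nm <- .par_names(model_tag)
  tr <- .par_transforms(model_tag)
  stopifnot(length(raw_draw) == length(nm))
  raw_draw <- as.numeric(raw_draw)
  nat <- setNames(vapply(seq_along(nm), function(i)
    .apply_transform(raw_draw[i], tr[[i]]), numeric(1)), nm)
  if (model_tag == "spdm") {
    spdm_params(nat[["a"]], nat[["z"]], nat[["t_er"]], nat[["d_spdm"]],
                nat[["gamma"]])
  } else {
    dpdm_params(nat[["a"]], nat[["z"]], nat[["t_er"]], nat[["d_utility"]],
                nat[["d_heuristic"]], nat[["delta"]], v_avg = v_avg)
  }
}

.check_mixed <- function(trials) {
  mixed <- trials$rem_left + trials$rem_right
  if (any(mixed != 1L))
    stop("drift construction requires mixed trials (exactly one option remembered)")
  invisible(TRUE)
}

#' SPDM trial drift rate
#'
#' `d_spdm * [rem_right * (v_right - gamma) - rem_left * (v_left - gamma)]`:
#' the remembered option's value is compared against the reference value
#' gamma, with positive drift pointing at the right/upper boundary.
#'
#' @param trials data.frame of mixed trials (see package conventions).
#' @param params an [spdm_params()] object.
#' @return numeric drift vector (evidence units per second).
#' @export
spdm_drift <- function(trials, params) {
  stopifnot(inherits(params, "spdm_params"))
  .check_mixed(trials)
  params$d_spdm * (trials$rem_right * (trials$v_right - params$gamma) -
                   trials$rem_left * (trials$v_left - params$gamma))
}

#' DPDM component drift rates
#'
#' The utility component compares the remembered value against `v_avg`;
#' the heuristic component has constant magnitude `d_heuristic` directed at
#' the remembered option, independent of value.
#'
#' @param trials data.frame of mixed trials.
#' @param params a [dpdm_params()] object.
#' @return data.frame with columns `utility` and `heuristic`.
#' @export
dpdm_drifts <- function(trials, params) {
  stopifnot(inherits(params, "dpdm_params"))
  .check_mixed(trials)
  data.frame(
    utility = params$d_utility *
      (trials$rem_right * (trials$v_right - params$v_avg) -
       trials$rem_left * (trials$v_left - params$v_avg)),
    heuristic = params$d_heuristic * (trials$rem_right - trials$rem_left))
}

.responded <- function(trials) {
  if (any(trials$response == "none"))
    stop("likelihood is defined only for trials with a response")
  invisible(TRUE)
}

#' SPDM trial log-likelihood
#'
#' Wiener log density of (response side, RT) at the SPDM drift; the right
#' response maps to the upper boundary.
#'
#' @param trials data.frame of responded mixed trials.
#' @param params an [spdm_params()] object.
#' @param noise diffusion noise sigma.
#' @return per-trial log density (`-Inf` where `rt_s <= t_er`).
#' @export
spdm_trial_loglik <- function(trials, params, noise = 1) {
  .responded(trials)
  v <- spdm_drift(trials, params)
  wp <- wiener_params(0, params$a, params$z, params$t_er, noise)
  fpt_log_density(trials$rt_s, trials$response == "right", wp, drift = v)
}

#' DPDM trial log-likelihood
#'
#' Log of the delta-weighted mixture of the utility-process and
#' heuristic-process Wiener densities. The two components share a, z and
#' T_er and differ only in drift; the per-trial process indicator is
#' marginalized analytically.
#'
#' @param trials data.frame of responded mixed trials.
#' @param params a [dpdm_params()] object.
#' @param noise diffusion noise sigma.
#' @return per-trial log density.
#' @export
dpdm_trial_loglik <- function(trials, params, noise = 1) {
  .responded(trials)
  dv <- dpdm_drifts(trials, params)
  wp <- wiener_params(0, params$a, params$z, params$t_er, noise)
  up <- trials$response == "right"
  lu <- log(params$delta) + fpt_log_density(trials$rt_s, up, wp, drift = dv$utility)
  lh <- log1p(-params$delta) + fpt_log_density(trials$rt_s, up, wp, drift = dv$heuristic)
  m <- pmax(lu, lh)
  ifelse(is.finite(m), m + log(exp(lu - m) + exp(lh - m)), -Inf)
}
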