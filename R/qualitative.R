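# Qualitative test battery: the shifted-quadratic RT regression whose
# group-level shift separates the two accounts, a Savage-Dickey Bayes
# factor for that shift, the hierarchical logistic model of the memory
# bias on choice, and the Bayesian correlation linking the two biases.

#' Fit the hierarchical shifted-quadratic RT model
#'
#' `rt_logz ~ Normal(b0_s + b1_s * (v_rem + b2_s)^2, sd_resid)` with
#' subject-level betas drawn from group normals. The peak of the fitted RT
#' curve sits at `v_rem = -b2`; the single-process account predicts a
#' positive group shift `mu_b2` (peak at a negative remembered value), the
#' dual-process account predicts `mu_b2 = 0`.
#'
#' @param trials filtered mixed trials; `rt_logz` is computed (per
#'   participant) if missing.
#' @param config a [sampler_config()].
#' @return `posterior_draws` over the quadratic-model parameters.
#' @export
fit_rt_quadratic <- function(trials, config = sampler_config()) {
  sample_posterior(rt_quadratic_model(), trials, config, store_loglik = FALSE)
}

#' Savage-Dickey Bayes factor for a nested point hypothesis
#'
#' `BF10 = prior density at 0 / posterior density at 0`, the posterior
#' density estimated by a Gaussian kernel density estimate with fixed
#' bandwidth (default 0.1 on the sampled scale). Used to test whether the
#' group-level RT-curve shift differs from zero (the dual-process account
#' is nested at `mu_b2 = 0`).
#'
#' @param posterior_samples draws of the parameter under test (>= 1000
#'   recommended).
#' @param prior_density function giving the prior density; default the
#'   standard normal prior of the RT model (density 0.3989 at 0).
#' @param kde_bandwidth Gaussian kernel bandwidth.
#' @param at nested null value (default 0).
#' @return object of class `savage_dickey` with elements `bf10`,
#'   `posterior_density`, `prior_density`, `bandwidth`, `lower_bound`
#'   (TRUE when the KDE density underflowed and `bf10` is a lower bound).
#' @export
savage_dickey_bf <- function(posterior_samples, prior_density = dnorm,
                             kde_bandwidth = 0.1, at = 0) {
  stopifnot(is.numeric(posterior_samples), length(posterior_samples) >= 2)
  if (length(posterior_samples) < 1000)
    warning("fewer than 1000 posterior samples; the KDE estimate may be unstable")
  p0 <- prior_density(at)
  post0 <- mean(dnorm(at, mean = posterior_samples, sd = kde_bandwidth))
  floor_d <- .Machine$double.xmin * 1e10
  lower_bound <- post0 < floor_d
  if (lower_bound) post0 <- floor_d
  structure(list(bf10 = p0 / post0, posterior_density = post0,
                 prior_density = p0, bandwidth = kde_bandwidth, at = at,
                 lower_bound = lower_bound),
            class = "savage_dickey")
}

#' @export
print.savage_dickey <- function(x, ...) {
  cat(sprintf("Savage-Dickey BF10 %s%.4g (prior %.4f, posterior %.3g at %g, bw %g)\n",
              if (x$lower_bound) ">= " else "", x$bf10, x$prior_density,
              x$posterior_density, x$at, x$bandwidth))
  invisible(x)
}

#' Fit the hierarchical logistic model of the memory bias on choice
#'
#' `logit P(choose remembered) = intercept_s + slope_s * v_rem` with
#' hierarchical normals on both coefficients. A positive group intercept
#' means the remembered option is preferred even at the average snack
#' value — the memory bias on choice. The slope makes the intercept
#' interpretable as the shift at `v_rem = 0`.
#'
#' @param trials filtered mixed trials.
#' @param config a [sampler_config()].
#' @return `posterior_draws` over intercepts and slopes.
#' @export
fit_choice_logistic <- function(trials, config = sampler_config()) {
  if (nrow(trials) == 0) stop("no trials to fit")
  sample_posterior(choice_logistic_model(), trials, config,
                   store_loglik = FALSE)
}

#' Bayesian correlation of two per-participant bias measures
#'
#' Bivariate-normal model with a uniform prior on the correlation over
#' (-1, 1) and weakly informative priors on the (standardized) locations
#' and scales, sampled by adaptive random-walk Metropolis. Returns the
#' posterior median correlation and its HDI.
#'
#' @param x,y equal-length numeric vectors (>= 5 participants), e.g.
#'   per-participant posterior medians of the choice-bias intercept and of
#'   the RT-curve shift b2.
#' @param config a [sampler_config()] (defaults to 2 chains x 4000).
#' @param prob HDI mass.
#' @return object of class `bias_correlation` with elements `r` (posterior
#'   median), `hdi`, and `draws`.
#' @export
correlate_bias <- function(x, y, config = NULL, prob = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a zero-variance vector")
  if (is.null(config)) config <- sampler_config(n_chains = 2, n_iter = 4000)
  xs <- (x - mean(x)) / sd(x)
  ys <- (y - mean(y)) / sd(y)
  # parameters: mu1, mu2, log s1, log s2, atanh(r); uniform prior on r
  # carries the Jacobian (1 - r^2) of the atanh parameterization
  logpost <- function(p) {
    s1 <- exp(p[3]); s2 <- exp(p[4]); r <- tanh(p[5])
    om <- 1 - r^2
    if (om <= 0 || !is.finite(s1) || !is.finite(s2)) return(-Inf)
    z1 <- (xs - p[1]) / s1; z2 <- (ys - p[2]) / s2
    q <- (z1^2 - 2 * r * z1 * z2 + z2^2) / om
    ll <- sum(-log(2 * pi) - log(s1) - log(s2) - 0.5 * log(om) - q / 2)
    lp <- dnorm(p[1], 0, 2, log = TRUE) + dnorm(p[2], 0, 2, log = TRUE) -
      s1^2 / 8 - s2^2 / 8 + p[3] + p[4] +  # half-N(0,2) scales + Jacobians
      log(om)                              # uniform r on atanh scale
    ll + lp
  }
  fit <- sample_posterior(
    custom_model(logpost, init = c(0, 0, 0, 0, atanh(min(0.9, max(-0.9, cor(xs, ys)))) ),
                 par_names = c("mu1", "mu2", "log_s1", "log_s2", "atanh_r")),
    config = config)
  rdraws <- tanh(extract_draws(fit, "atanh_r"))
  structure(list(r = median(rdraws), hdi = .hdi_from_samples(rdraws, prob),
                 draws = rdraws, n = length(x)),
            class = "bias_correlation")
}

#' @export
print.bias_correlation <- function(x, ...) {
  cat(sprintf("Bayesian correlation r = %.3f, 95%% HDI [%.3f, %.3f] (n = %d)\n",
              x$r, x$hdi[["lower"]], x$hdi[["upper"]], x$n))
  invisible(x)
}

#' Run the full qualitative battery
#'
#' Fits the shifted-quadratic RT model and the logistic choice model,
#' computes the Savage-Dickey Bayes factor for the group RT shift, and
#' correlates the two per-participant bias measures.
#'
#' @param trials filtered, annotated mixed trials.
#' @param config a [sampler_config()].
#' @param kde_bandwidth Savage-Dickey KDE bandwidth.
#' @return list with `rt_fit`, `choice_fit`, `bf` (savage_dickey),
#'   `correlation` (bias_correlation) and a one-row `summary` data.frame.
#' @export
qualitative_battery <- function(trials, config = sampler_config(),
                                kde_bandwidth = 0.1) {
  rt_fit <- fit_rt_quadratic(trials, config)
  choice_fit <- fit_choice_logistic(trials, config)
  mu_b2 <- extract_draws(rt_fit, "mu_b2")
  bf <- savage_dickey_bf(mu_b2, kde_bandwidth = kde_bandwidth)
  corr <- correlate_bias(subject_medians(choice_fit, "intercept"),
                         subject_medians(rt_fit, "b2"),
                         config = sampler_config(n_chains = 2, n_iter = 4000,
                                                 seed = config$seed))
  h2 <- .hdi_from_samples(mu_b2)
  ic <- extract_draws(choice_fit, "mu_intercept")
  hi <- .hdi_from_samples(ic)
  summary <- data.frame(
    mu_b2_mean = mean(mu_b2), mu_b2_hdi_lower = h2[["lower"]],
    mu_b2_hdi_upper = h2[["upper"]], bf10 = bf$bf10,
    choice_intercept_mean = mean(ic), choice_intercept_hdi_lower = hi[["lower"]],
    choice_intercept_hdi_upper = hi[["upper"]],
    bias_correlation = corr$r, bias_correlation_hdi_lower = corr$hdi[["lower"]],
    bias_correlation_hdi_upper = corr$hdi[["upper"]])
  list(rt_fit = rt_fit, choice_fit = choice_fit, bf = bf,
       correlation = corr, summary = summary)
}
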