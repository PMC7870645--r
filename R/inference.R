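# Hierarchical Bayesian inference. All built-in models share the same
# structure: unconstrained subject-level parameters drawn from per-parameter
# normal group distributions N(mu_k, sigma_k), with weakly informative
# normal priors on the locations and half-normal priors on the scales.
# Posteriors are sampled with an adaptive Metropolis-within-Gibbs scheme
# implemented in C++ (random-walk subject updates adapted toward 0.44
# acceptance, conjugate Gibbs updates for group means, random-walk updates
# on log group scales).

#' Sampler configuration
#'
#' @param n_chains number of independent chains (>= 2 for convergence
#'   diagnostics; default 4).
#' @param n_iter iterations per chain, including warmup (default 10000).
#' @param warmup_fraction fraction of iterations discarded as warmup
#'   (adaptation happens only during warmup; default 0.5).
#' @param seed integer seed; every fit is reproducible from it.
#' @param thin keep every `thin`-th post-warmup draw.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4L, n_iter = 10000L,
                           warmup_fraction = 0.5, seed = 1L, thin = 1L) {
  stopifnot(n_chains >= 1, n_iter >= 20, warmup_fraction > 0,
            warmup_fraction < 1, thin >= 1)
  if (n_chains < 2)
    warning("convergence diagnostics (rhat) require at least 2 chains")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 warmup_fraction = warmup_fraction, seed = as.integer(seed),
                 thin = as.integer(thin)),
            class = "sampler_config")
}

# ---- model constructors ---------------------------------------------------

.new_model <- function(tag, par_names, prior_mu_sd, prior_sigma_sd,
                       transforms, extra = list()) {
  structure(c(list(tag = tag, par_names = par_names,
                   prior_mu_sd = prior_mu_sd, prior_sigma_sd = prior_sigma_sd,
                   transforms = transforms), extra),
            class = c(paste0("memddm_", tag, "_model"), "memddm_model"))
}

#' Hierarchical single-process diffusion model
#'
#' Subject parameters a, z, T_er, d_spdm, gamma (positive parameters via
#' exp, z via the standard-normal CDF, gamma untransformed). Group
#' locations have Normal(0, 2) priors on the unconstrained scale and group
#' scales half-Normal(0, 1) priors (weakly informative; configurable).
#'
#' @param noise diffusion noise sigma (scaling convention; default 1).
#' @param prior_mu_sd,prior_sigma_sd prior scales, recycled over the 5
#'   parameters.
#' @return model object for [sample_posterior()].
#' @export
spdm_model <- function(noise = 1, prior_mu_sd = 2, prior_sigma_sd = 1) {
  nm <- .par_names("spdm")
  .new_model("spdm", nm, rep_len(prior_mu_sd, 5), rep_len(prior_sigma_sd, 5),
             .par_transforms("spdm"), list(noise = noise, model_id = 1L))
}

#' Hierarchical dual-process diffusion model
#'
#' Subject parameters a, z, T_er, d_utility, d_heuristic, delta. The
#' per-trial process indicator is marginalized analytically inside the
#' mixture likelihood. Both components share a, z and T_er.
#'
#' @param noise diffusion noise sigma.
#' @param v_avg utility-process reference value (0 for centered values).
#' @param prior_mu_sd,prior_sigma_sd prior scales, recycled over the 6
#'   parameters.
#' @return model object for [sample_posterior()].
#' @export
dpdm_model <- function(noise = 1, v_avg = 0, prior_mu_sd = 2,
                       prior_sigma_sd = 1) {
  nm <- .par_names("dpdm")
  .new_model("dpdm", nm, rep_len(prior_mu_sd, 6), rep_len(prior_sigma_sd, 6),
             .par_transforms("dpdm"),
             list(noise = noise, v_avg = v_avg, model_id = 2L))
}

#' Hierarchical shifted-quadratic RT regression
#'
#' `rt_logz ~ Normal(b0_s + b1_s * (v_rem + b2_s)^2, sd_resid)`: the
#' horizontal shift b2 locates the RT-curve peak at `v_rem = -b2`, so a
#' positive group-level shift is the RT signature of a biased reference
#' value. Priors: standard normal on group locations, standard half-normal
#' on group scales and the residual scale.
#'
#' @return model object for [sample_posterior()].
#' @export
rt_quadratic_model <- function() {
  nm <- c("b0", "b1", "b2")
  .new_model("rt_quadratic", nm, rep(1, 3), rep(1, 3),
             c(b0 = "identity", b1 = "identity", b2 = "identity"),
             list(model_id = 3L))
}

#' Hierarchical logistic model of the memory bias on choice
#'
#' `logit P(choose remembered) = intercept_s + slope_s * v_rem`. A positive
#' group intercept is the memory bias on choice: at the average snack value
#' the remembered option is chosen more often than not.
#'
#' @return model object for [sample_posterior()].
#' @export
choice_logistic_model <- function() {
  nm <- c("intercept", "slope")
  .new_model("choice_logistic", nm, rep(1, 2), rep(1, 2),
             c(intercept = "identity", slope = "identity"),
             list(model_id = 4L))
}

#' Non-hierarchical model from a user-supplied log posterior
#'
#' Sampled with the same adaptive random-walk scheme at the R level; used
#' for small auxiliary models and for validating the sampler against
#' closed-form posteriors.
#'
#' @param log_density function of the parameter vector returning the
#'   (unnormalized) log posterior.
#' @param init numeric initialization vector.
#' @param par_names parameter names.
#' @return model object for [sample_posterior()].
#' @export
custom_model <- function(log_density, init, par_names = NULL) {
  stopifnot(is.function(log_density), is.numeric(init))
  if (is.null(par_names)) par_names <- paste0("par", seq_along(init))
  structure(list(tag = "custom", log_density = log_density, init = init,
                 par_names = par_names),
            class = c("memddm_custom_model", "memddm_model"))
}

# ---- fitting --------------------------------------------------------------

#' Draw posterior samples for a model
#'
#' @param model a model object ([spdm_model()], [dpdm_model()],
#'   [rt_quadratic_model()], [choice_logistic_model()] or
#'   [custom_model()]).
#' @param data for the built-in models, a filtered mixed-trial data.frame
#'   (with `rt_logz` for the quadratic model; `v_rem`/`chose_rem` columns
#'   are derived if absent). Ignored for custom models.
#' @param config a [sampler_config()].
#' @param store_loglik keep per-trial pointwise log-likelihoods for every
#'   stored draw (needed for WAIC).
#' @return object of class `posterior_draws`: array of draws indexed
#'   (chain, iteration, parameter), optional pointwise log-likelihood
#'   array, and model metadata.
#' @export
sample_posterior <- function(model, data = NULL, config = sampler_config(),
                             store_loglik = TRUE) {
  UseMethod("sample_posterior")
}

#' @export
sample_posterior.memddm_model <- function(model, data = NULL,
                                          config = sampler_config(),
                                          store_loglik = TRUE) {
  stopifnot(inherits(config, "sampler_config"), is.data.frame(data))
  tag <- model$tag
  trials <- annotate_memory(data)
  if (tag %in% c("spdm", "dpdm")) {
    .responded(trials)
    if (any(trials$rt_s <= 0)) stop("RTs must be positive")
  }
  if (tag == "rt_quadratic" && !"rt_logz" %in% names(trials))
    trials <- standardize_rts(trials)
  part <- factor(trials$participant)
  n_subj <- nlevels(part)
  if (tag %in% c("rt_quadratic", "choice_logistic") && n_subj < 2)
    stop("hierarchical models need at least 2 participants")
  ord <- order(as.integer(part))
  trials <- trials[ord, , drop = FALSE]
  idx <- as.integer(part)[ord] - 1L
  n <- nrow(trials)
  zero <- numeric(n)
  args <- switch(tag,
    spdm = list(resp = as.integer(trials$response == "right"),
                rt = trials$rt_s, x = trials$v_rem, s = trials$mem_side,
                y = zero, sigma = model$noise, vavg = 0),
    dpdm = list(resp = as.integer(trials$response == "right"),
                rt = trials$rt_s, x = trials$v_rem, s = trials$mem_side,
                y = zero, sigma = model$noise, vavg = model$v_avg),
    rt_quadratic = list(resp = integer(n), rt = zero, x = trials$v_rem,
                        s = zero, y = trials$rt_logz, sigma = 1, vavg = 0),
    choice_logistic = list(resp = as.integer(trials$chose_rem), rt = zero,
                           x = trials$v_rem, s = zero, y = zero, sigma = 1,
                           vavg = 0))
  n_warmup <- as.integer(floor(config$n_iter * config$warmup_fraction))
  set.seed(config$seed)
  raw <- hier_mwg_cpp(model$model_id, idx, args$resp, args$rt, args$x,
                      args$s, args$y, n_subj, args$sigma, args$vavg,
                      model$prior_mu_sd, model$prior_sigma_sd,
                      config$n_chains, config$n_iter, n_warmup, config$thin,
                      store_loglik)
  nm <- model$par_names
  pnames <- c(paste0("mu_", nm), paste0("sigma_", nm),
              if (model$model_id == 3L) "sd_resid",
              unlist(lapply(nm, function(k)
                paste0(k, "[", seq_len(n_subj), "]"))))
  draws <- raw$draws
  dimnames(draws) <- list(NULL, NULL, pnames)
  structure(list(draws = draws, log_lik = raw$log_lik,
                 model_tag = tag, par_names = nm,
                 transforms = model$transforms, n_subjects = n_subj,
                 participants = levels(part), n_trials = n,
                 trial_order = ord, config = config,
                 noise = model$noise %||% 1, v_avg = model$v_avg %||% 0),
            class = "posterior_draws")
}

#' @export
sample_posterior.memddm_custom_model <- function(model, data = NULL,
                                                 config = sampler_config(),
                                                 store_loglik = FALSE) {
  stopifnot(inherits(config, "sampler_config"))
  P <- length(model$init)
  n_warmup <- as.integer(floor(config$n_iter * config$warmup_fraction))
  n_kept <- length(seq(n_warmup + 1L, config$n_iter, by = config$thin))
  draws <- array(NA_real_, c(config$n_chains, n_kept, P),
                 dimnames = list(NULL, NULL, model$par_names))
  set.seed(config$seed)
  f <- model$log_density
  for (cc in seq_len(config$n_chains)) {
    x <- model$init + 0.1 * rnorm(P)
    lp <- f(x)
    if (!is.finite(lp)) { x <- model$init; lp <- f(x) }
    if (!is.finite(lp)) stop("log density not finite at initialization")
    leps <- rep(log(0.5), P)
    ki <- 0L
    for (it in seq_len(config$n_iter)) {
      astep <- 1 / sqrt(it)
      for (p in seq_len(P)) {
        xp <- x
        xp[p] <- x[p] + exp(leps[p]) * rnorm(1)
        lpp <- f(xp)
        if (!is.finite(lpp)) lpp <- -Inf
        la <- lpp - lp
        acc <- if (is.finite(la)) min(1, exp(la)) else as.numeric(isTRUE(la > 0))
        if (runif(1) < acc) { x <- xp; lp <- lpp }
        if (it <= n_warmup) leps[p] <- leps[p] + astep * (acc - 0.44)
      }
      if (it > n_warmup && (it - n_warmup - 1L) %% config$thin == 0L) {
        ki <- ki + 1L
        draws[cc, ki, ] <- x
      }
    }
  }
  structure(list(draws = draws, log_lik = NULL, model_tag = "custom",
                 par_names = model$par_names, transforms = NULL,
                 n_subjects = 0L, n_trials = NA_integer_, config = config),
            class = "posterior_draws")
}

# ---- posterior-draws utilities --------------------------------------------

#' Extract draws of one parameter as a vector
#'
#' @param fit a `posterior_draws` object.
#' @param par parameter name (see `dimnames(fit$draws)[[3]]`).
#' @return numeric vector pooling all chains.
#' @export
extract_draws <- function(fit, par) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (!par %in% dimnames(fit$draws)[[3]]) stop("unknown parameter: ", par)
  as.vector(fit$draws[, , par])
}

#' Per-participant posterior medians of a subject-level parameter
#'
#' @param fit a `posterior_draws` object from a hierarchical fit.
#' @param par subject-level parameter name (e.g. `"gamma"`,
#'   `"intercept"`).
#' @return numeric vector, one median per participant (raw scale).
#' @export
subject_medians <- function(fit, par) {
  stopifnot(inherits(fit, "posterior_draws"), fit$n_subjects >= 1)
  vapply(seq_len(fit$n_subjects), function(s)
    median(extract_draws(fit, paste0(par, "[", s, "]"))), numeric(1))
}

#' Pointwise log-likelihood matrix
#'
#' @param fit a `posterior_draws` object fitted with
#'   `store_loglik = TRUE`.
#' @return matrix (draws x trials), chains stacked, trials in the original
#'   row order of the data passed to [sample_posterior()].
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (is.null(fit$log_lik)) stop("fit was run without store_loglik")
  ll <- fit$log_lik
  d <- dim(ll)
  m <- matrix(ll, d[1] * d[2], d[3])
  if (!is.null(fit$trial_order)) m[, order(fit$trial_order), drop = FALSE] else m
}

#' @export
summary.posterior_draws <- function(object, prob = 0.95, group_only = FALSE, ...) {
  pn <- dimnames(object$draws)[[3]]
  if (group_only) pn <- grep("^(mu_|sigma_|sd_)", pn, value = TRUE)
  rh <- if (dim(object$draws)[1] >= 2) rhat(object) else NULL
  rows <- lapply(pn, function(p) {
    x <- extract_draws(object, p)
    h <- .hdi_from_samples(x, prob)
    data.frame(parameter = p, mean = mean(x), median = median(x),
               hdi_lower = h[["lower"]], hdi_upper = h[["upper"]],
               rhat = if (is.null(rh)) NA_real_ else rh[[p]])
  })
  do.call(rbind, rows)
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("posterior_draws: model '%s', %d chains x %d draws, %d parameters\n",
              x$model_tag, d[1], d[2], d[3]))
  invisible(x)
}

#' Group-level summary on the natural scale
#'
#' Reports each group location through its parameter transformation
#' (exp for positive parameters, the normal CDF for interval parameters)
#' and each group scale as `exp(sigma)` — the reporting convention adopted
#' by this package for scale parameters, documented rather than assumed
#' universal.
#'
#' @param fit a hierarchical `posterior_draws` object.
#' @param prob HDI mass.
#' @return data.frame of transformed posterior means and HDIs.
#' @export
group_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "posterior_draws"), !is.null(fit$transforms))
  rows <- lapply(fit$par_names, function(k) {
    tr <- fit$transforms[[k]]
    mu <- .apply_transform(extract_draws(fit, paste0("mu_", k)), tr)
    sg <- exp(extract_draws(fit, paste0("sigma_", k)))
    hm <- .hdi_from_samples(mu, prob); hs <- .hdi_from_samples(sg, prob)
    data.frame(parameter = c(paste0("mu_", k), paste0("sigma_", k)),
               mean = c(mean(mu), mean(sg)),
               hdi_lower = c(hm[["lower"]], hs[["lower"]]),
               hdi_upper = c(hm[["upper"]], hs[["upper"]]))
  })
  do.call(rbind, rows)
}

# ---- diagnostics and model comparison -------------------------------------

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin statistic computed after splitting each chain in half;
#' values at or below 1.01 for every parameter are taken as converged.
#'
#' @param fit a `posterior_draws` object (or a chains x draws x parameters
#'   array) with at least 2 chains.
#' @return named vector of R-hat values.
#' @export
rhat <- function(fit) {
  a <- if (inherits(fit, "posterior_draws")) fit$draws else fit
  stopifnot(is.array(a), length(dim(a)) == 3)
  d <- dim(a)
  if (d[1] < 2) stop("rhat requires at least 2 chains")
  half <- d[2] %/% 2L
  if (half < 2) stop("rhat requires at least 4 draws per chain")
  out <- vapply(seq_len(d[3]), function(p) {
    segs <- c(lapply(seq_len(d[1]), function(cc) a[cc, seq_len(half), p]),
              lapply(seq_len(d[1]), function(cc) a[cc, half + seq_len(half), p]))
    means <- vapply(segs, mean, numeric(1))
    vars <- vapply(segs, var, numeric(1))
    W <- mean(vars)
    B <- half * var(means)
    if (W == 0) return(if (B > 0) Inf else 1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  names(out) <- dimnames(a)[[3]]
  out
}

#' Widely applicable information criterion
#'
#' `WAIC = -2 * (lppd - p_waic)` with `p_waic` the summed posterior
#' variance of the pointwise log-likelihoods. The pointwise vector is
#' retained for standard errors of WAIC differences.
#'
#' @param log_lik matrix of pointwise log-likelihoods (draws x trials), as
#'   from [pointwise_loglik()], with at least 2 draws.
#' @return object of class `waic_result` with elements `waic`, `lppd`,
#'   `p_waic`, `pointwise`.
#' @export
waic <- function(log_lik) {
  stopifnot(is.matrix(log_lik), nrow(log_lik) >= 2)
  if (!all(is.finite(log_lik)))
    stop("pointwise log-likelihood matrix contains non-finite values")
  S <- nrow(log_lik)
  lppd_i <- apply(log_lik, 2, function(x) {
    m <- max(x); m + log(mean(exp(x - m)))
  })
  p_i <- apply(log_lik, 2, var)
  pointwise <- -2 * (lppd_i - p_i)
  structure(list(waic = sum(pointwise), lppd = sum(lppd_i),
                 p_waic = sum(p_i), pointwise = pointwise),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.2f (lppd %.2f, p_waic %.2f, n = %d)\n",
              x$waic, x$lppd, x$p_waic, length(x$pointwise)))
  invisible(x)
}

#' Compare two models by WAIC
#'
#' Difference `WAIC_A - WAIC_B` (negative favors A), its standard error
#' `sqrt(n) * sd` of the pointwise WAIC differences, and the standardized
#' effect size (difference / SE).
#'
#' @param waic_a,waic_b [waic()] results on the same trials in the same
#'   order.
#' @param labels model labels for printing.
#' @return object of class `model_comparison`.
#' @export
compare_waic <- function(waic_a, waic_b, labels = c("A", "B")) {
  stopifnot(inherits(waic_a, "waic_result"), inherits(waic_b, "waic_result"))
  n <- length(waic_a$pointwise)
  if (length(waic_b$pointwise) != n)
    stop("models were evaluated on different numbers of trials")
  d <- waic_a$pointwise - waic_b$pointwise
  diff <- sum(d)
  se <- sqrt(n) * sd(d)
  eff <- if (se == 0) { if (diff == 0) 0 else sign(diff) * Inf } else diff / se
  structure(list(labels = labels, waic_a = waic_a$waic, waic_b = waic_b$waic,
                 waic_difference = diff, se_of_difference = se,
                 standardized_effect = eff,
                 preferred = labels[if (diff <= 0) 1 else 2]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("WAIC %s: %.2f | %s: %.2f\n", x$labels[1], x$waic_a,
              x$labels[2], x$waic_b))
  cat(sprintf("difference (%s - %s) %.2f, SE %.2f, standardized effect %.2f\n",
              x$labels[1], x$labels[2], x$waic_difference,
              x$se_of_difference, x$standardized_effect))
  cat("preferred model:", x$preferred, "\n")
  invisible(x)
}
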