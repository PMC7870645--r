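# Absolute-performance and identifiability surface: posterior predictive
# checks on binned choice/RT curves, parameter recovery, model recovery.

#' Posterior predictive check on binned choice and RT curves
#'
#' Simulates `n_replicates` replicate experiments from the fitted model.
#' In each replicate, every agent's parameter vector is drawn at random
#' from that participant's posterior (per agent, per replicate); the
#' agent's trials are re-simulated (for the DPDM each trial's governing
#' process is a fresh Bernoulli(delta_s) draw), and choices and RTs are
#' aggregated into bins over the remembered option's value. Returns the
#' per-bin 95% HDI of the replicate means next to the empirical bin means.
#'
#' @param fit `posterior_draws` from [sample_posterior()] with an SPDM or
#'   DPDM model.
#' @param trials the filtered mixed-trial data.frame the model was fitted
#'   to.
#' @param n_replicates number of simulated experiments (default 500).
#' @param n_bins number of value bins (default 8).
#' @param binning `"quantile"` (equal-count octiles, default) or
#'   `"width"` (equal-width bins).
#' @param time_step,max_time simulator settings.
#' @param prob HDI mass.
#' @return object of class `binned_prediction`: `bins` data.frame with
#'   empirical means and simulated HDIs, plus the replicate mean matrices.
#' @export
posterior_predictive <- function(fit, trials, n_replicates = 500L,
                                 n_bins = 8L, binning = c("quantile", "width"),
                                 time_step = 1e-3, max_time = 10,
                                 prob = 0.95) {
  stopifnot(inherits(fit, "posterior_draws"),
            fit$model_tag %in% c("spdm", "dpdm"), n_replicates >= 1)
  binning <- match.arg(binning)
  trials <- annotate_memory(trials)
  d <- dim(fit$draws)
  n_draws <- d[1] * d[2]
  resampled <- n_draws < n_replicates
  if (resampled)
    warning("fewer distinct posterior vectors than replicates; sampling with replacement")
  edges <- if (binning == "quantile") {
    unique(quantile(trials$v_rem, probs = seq(0, 1, length.out = n_bins + 1)))
  } else {
    seq(min(trials$v_rem), max(trials$v_rem), length.out = n_bins + 1)
  }
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  nb <- length(edges) - 1L
  bin_of <- cut(trials$v_rem, edges, labels = FALSE)
  bin_means <- function(x, ok = rep(TRUE, length(x))) {
    vapply(seq_len(nb), function(b) {
      i <- ok & bin_of == b
      if (any(i)) mean(x[i]) else NA_real_
    }, numeric(1))
  }
  emp_choice <- bin_means(trials$chose_rem)
  emp_rt <- bin_means(trials$rt_s)
  subj_rows <- split(seq_len(nrow(trials)), trials$participant)
  K <- length(fit$par_names)
  choice_rep <- matrix(NA_real_, n_replicates, nb)
  rt_rep <- matrix(NA_real_, n_replicates, nb)
  for (r in seq_len(n_replicates)) {
    sim_rem <- numeric(nrow(trials)); sim_rt <- numeric(nrow(trials))
    ok <- logical(nrow(trials))
    for (s in seq_along(subj_rows)) {
      idx <- subj_rows[[s]]
      j <- sample.int(n_draws, 1)
      cc <- (j - 1L) %% d[1] + 1L; it <- (j - 1L) %/% d[1] + 1L
      raw <- vapply(fit$par_names, function(k)
        fit$draws[cc, it, paste0(k, "[", s, "]")], numeric(1))
      p <- transform_subject_draw(raw, fit$model_tag, v_avg = fit$v_avg)
      tr <- trials[idx, ]
      if (fit$model_tag == "spdm") {
        v <- .gen_drift_spdm(tr, p)
      } else {
        k01 <- rbinom(length(idx), 1L, p$delta)
        v <- ifelse(k01 == 1L, .gen_drift_dpdm_utility(tr, p),
                    .gen_drift_dpdm_heuristic(tr, p))
      }
      wp <- wiener_params(0, p$a, p$z, p$t_er, fit$noise)
      sim <- simulate_trials(wp, drift = v, time_step = time_step,
                             max_time = max_time)
      ok[idx] <- !is.na(sim$hit_upper)
      sim_rem[idx] <- as.integer(sim$hit_upper == (tr$mem_side > 0))
      sim_rt[idx] <- sim$rt
    }
    choice_rep[r, ] <- bin_means(sim_rem, ok)
    rt_rep[r, ] <- bin_means(sim_rt, ok)
  }
  hdis <- function(m) t(apply(m, 2, function(x) .hdi_from_samples(x[is.finite(x)], prob)))
  hc <- hdis(choice_rep); hr <- hdis(rt_rep)
  bins <- data.frame(
    bin = seq_len(nb),
    v_rem_mid = vapply(seq_len(nb), function(b) median(trials$v_rem[bin_of == b]),
                       numeric(1)),
    emp_choice = emp_choice, choice_hdi_lower = hc[, 1], choice_hdi_upper = hc[, 2],
    sim_choice_mean = colMeans(choice_rep, na.rm = TRUE),
    emp_rt = emp_rt, rt_hdi_lower = hr[, 1], rt_hdi_upper = hr[, 2],
    sim_rt_mean = colMeans(rt_rep, na.rm = TRUE))
  structure(list(bins = bins, choice_replicates = choice_rep,
                 rt_replicates = rt_rep, n_replicates = n_replicates,
                 model_tag = fit$model_tag, resampled = resampled),
            class = "binned_prediction")
}

#' @export
print.binned_prediction <- function(x, ...) {
  cat(sprintf("posterior predictive (%s, %d replicates, %d bins)\n",
              x$model_tag, x$n_replicates, nrow(x$bins)))
  print(x$bins, digits = 3)
  invisible(x)
}

#' Plot a binned posterior predictive check
#'
#' Choice-rate and RT panels: empirical bin means (points) inside the
#' simulated 95% HDI bands.
#'
#' @param x a `binned_prediction`.
#' @param ... ignored.
#' @export
plot.binned_prediction <- function(x, ...) {
  b <- x$bins
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (panel in c("choice", "rt")) {
    lo <- b[[paste0(panel, "_hdi_lower")]]; hi <- b[[paste0(panel, "_hdi_upper")]]
    emp <- b[[paste0("emp_", panel)]]
    graphics::plot(b$v_rem_mid, emp, ylim = range(c(lo, hi, emp), na.rm = TRUE),
                   xlab = "value of remembered option",
                   ylab = if (panel == "choice") "P(choose remembered)" else "mean RT (s)",
                   pch = 19, main = x$model_tag)
    graphics::arrows(b$v_rem_mid, lo, b$v_rem_mid, hi, angle = 90, code = 3,
                     length = 0.04, col = "grey50")
  }
  invisible(x)
}

#' Parameter recovery study
#'
#' Simulates a study from known group-level truth, preprocesses it, refits
#' the generating model, and reports whether each group-level generating
#' value is covered by its 95% HDI together with the rank correlation of
#' true versus recovered (posterior-median) subject-level parameters.
#'
#' @param model_tag `"spdm"` or `"dpdm"`.
#' @param group generating [group_hyperparams()] (default
#'   [default_ground_truth()]).
#' @param design a [study_design()].
#' @param config a [sampler_config()] (reduced settings by default:
#'   2 chains x 1000 iterations).
#' @param rhat_threshold fits with any R-hat above this are flagged.
#' @return object of class `recovery_report`: `group` data.frame
#'   (generating value, posterior median, HDI, coverage flag per group
#'   parameter), `subject_cor` (Spearman correlations per subject-level
#'   parameter), `converged`, `fit`.
#' @export
parameter_recovery <- function(model_tag = c("spdm", "dpdm"), group = NULL,
                               design = study_design(),
                               config = sampler_config(n_chains = 2,
                                                       n_iter = 1000),
                               rhat_threshold = 1.01) {
  model_tag <- match.arg(model_tag)
  if (is.null(group)) group <- default_ground_truth(model_tag)
  sim <- simulate_study(design, model_tag, group)
  kept <- filter_trials(sim$trials)$kept
  model <- if (model_tag == "spdm") spdm_model() else dpdm_model()
  fit <- sample_posterior(model, kept, config, store_loglik = FALSE)
  rh <- rhat(fit)
  converged <- all(rh <= rhat_threshold, na.rm = TRUE)
  rows <- lapply(names(group$mu), function(k) {
    out <- lapply(c("mu", "sigma"), function(what) {
      par <- paste0(what, "_", k)
      x <- extract_draws(fit, par)
      h <- .hdi_from_samples(x, 0.95)
      truthv <- if (what == "mu") group$mu[[k]] else group$sigma[[k]]
      data.frame(parameter = par, generating = truthv, median = median(x),
                 hdi_lower = h[["lower"]], hdi_upper = h[["upper"]],
                 covered = truthv >= h[["lower"]] & truthv <= h[["upper"]])
    })
    do.call(rbind, out)
  })
  group_tab <- do.call(rbind, rows)
  subject_cor <- vapply(names(group$mu), function(k) {
    truthv <- sim$truth$subjects$raw[, k]
    est <- subject_medians(fit, k)
    suppressWarnings(cor(truthv, est, method = "spearman"))
  }, numeric(1))
  structure(list(model_tag = model_tag, group = group_tab,
                 subject_cor = subject_cor, converged = converged,
                 max_rhat = max(rh, na.rm = TRUE), fit = fit,
                 truth = sim$truth),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("parameter recovery (%s): %d/%d group parameters covered; %s\n",
              x$model_tag, sum(x$group$covered), nrow(x$group),
              if (x$converged) "converged"
              else sprintf("NOT converged (max rhat %.3f)", x$max_rhat)))
  print(x$group, digits = 3)
  cat("subject-level Spearman correlations:\n")
  print(round(x$subject_cor, 3))
  invisible(x)
}

#' Model recovery study
#'
#' Generates datasets from each model, fits both models to every dataset,
#' and records which model WAIC prefers, yielding a 2 x 2 confusion matrix
#' of generating versus preferred model.
#'
#' @param n_datasets datasets per generating model.
#' @param design a [study_design()].
#' @param config a [sampler_config()] (reduced settings by default).
#' @param groups named list with `spdm` and `dpdm` generating
#'   [group_hyperparams()] (defaults to [default_ground_truth()]).
#' @param rhat_threshold convergence flag threshold.
#' @return object of class `model_recovery_result`: `confusion` matrix,
#'   `details` data.frame (per dataset: generator, WAIC difference
#'   SPDM - DPDM, winner, convergence flags), `n_nonconverged`.
#' @export
model_recovery <- function(n_datasets = 10L, design = study_design(),
                           config = sampler_config(n_chains = 2,
                                                   n_iter = 1000),
                           groups = NULL, rhat_threshold = 1.01) {
  if (is.null(groups))
    groups <- list(spdm = default_ground_truth("spdm"),
                   dpdm = default_ground_truth("dpdm"))
  details <- list()
  for (gen in c("spdm", "dpdm")) {
    for (i in seq_len(n_datasets)) {
      des <- design
      des$rng_seed <- design$rng_seed + 7919L * (i + n_datasets * (gen == "dpdm"))
      sim <- simulate_study(des, gen, groups[[gen]])
      kept <- filter_trials(sim$trials)$kept
      cfg <- config; cfg$seed <- config$seed + i
      fa <- sample_posterior(spdm_model(), kept, cfg)
      fb <- sample_posterior(dpdm_model(), kept, cfg)
      cmp <- compare_waic(waic(pointwise_loglik(fa)),
                          waic(pointwise_loglik(fb)),
                          labels = c("spdm", "dpdm"))
      details[[length(details) + 1L]] <- data.frame(
        generator = gen, dataset = i,
        waic_diff_spdm_minus_dpdm = cmp$waic_difference,
        winner = cmp$preferred,
        converged = all(rhat(fa) <= rhat_threshold) &&
          all(rhat(fb) <= rhat_threshold))
    }
  }
  details <- do.call(rbind, details)
  confusion <- table(generator = factor(details$generator,
                                        c("spdm", "dpdm")),
                     preferred = factor(details$winner, c("spdm", "dpdm")))
  structure(list(confusion = confusion, details = details,
                 n_nonconverged = sum(!details$converged)),
            class = "model_recovery_result")
}

#' @export
print.model_recovery_result <- function(x, ...) {
  cat("model recovery confusion matrix (rows: generator, cols: WAIC winner)\n")
  print(x$confusion)
  if (x$n_nonconverged > 0)
    cat(sprintf("%d fit pair(s) flagged as non-converged\n", x$n_nonconverged))
  invisible(x)
}
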