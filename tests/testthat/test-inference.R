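# Sampler correctness, convergence diagnostics, WAIC machinery.

test_that("the sampler reproduces a conjugate normal-normal posterior", {
  # y ~ N(mu, 1), mu ~ N(0, 1): posterior N(n*ybar/(n+1), 1/sqrt(n+1))
  set.seed(42)
  y <- rnorm(25, 0.8, 1)
  n <- length(y); post_m <- n * mean(y) / (n + 1); post_s <- 1 / sqrt(n + 1)
  m <- custom_model(function(p) sum(dnorm(y, p, 1, log = TRUE)) +
                      dnorm(p, 0, 1, log = TRUE),
                    init = 0, par_names = "mu")
  fit <- sample_posterior(m, config = sampler_config(n_chains = 2,
                                                     n_iter = 6000, seed = 2))
  x <- extract_draws(fit, "mu")
  # generous Monte-Carlo error allowance for autocorrelated draws
  expect_lt(abs(mean(x) - post_m), 4 * post_s / sqrt(length(x) / 20))
  expect_lt(abs(sd(x) - post_s) / post_s, 0.1)
  expect_lt(max(rhat(fit)), 1.01)
  # determinism under the seed
  fit2 <- sample_posterior(m, config = sampler_config(n_chains = 2,
                                                      n_iter = 6000, seed = 2))
  expect_identical(fit$draws, fit2$draws)
})

test_that("hierarchical fits are reproducible and expose sane posteriors", {
  sim <- simulate_study(study_design(8, 60, rng_seed = 3), "spdm")
  kept <- filter_trials(sim$trials)$kept
  cfg <- quick_config(seed = 4, n_iter = 400)
  f1 <- sample_posterior(spdm_model(), kept, cfg)
  f2 <- sample_posterior(spdm_model(), kept, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$log_lik, f2$log_lik)
  expect_true(all(is.finite(f1$draws)))
  expect_true(all(is.finite(f1$log_lik)))
  # dimensions: 2K group + K * n_subjects subject parameters
  expect_equal(dim(f1$draws)[3], 10 + 5 * 8)
  expect_equal(dim(f1$log_lik)[3], nrow(kept))
  s <- summary(f1, group_only = TRUE)
  expect_equal(nrow(s), 10)
  expect_true(all(s$hdi_lower <= s$median & s$median <= s$hdi_upper))
  # natural-scale reporting uses the documented transformations
  g <- group_summary(f1)
  expect_equal(g$mean[g$parameter == "mu_a"],
               mean(exp(extract_draws(f1, "mu_a"))))
  expect_equal(g$mean[g$parameter == "mu_z"],
               mean(pnorm(extract_draws(f1, "mu_z"))))
})

test_that("split R-hat flags non-convergence and matches hand computation", {
  # well-mixed white noise: converged
  set.seed(1)
  a <- array(rnorm(4 * 400 * 2), c(4, 400, 2),
             dimnames = list(NULL, NULL, c("p1", "p2")))
  expect_true(all(rhat(a) < 1.01))
  # chains stuck at different means: far from converged
  b <- array(c(rnorm(400, 0, 1), rnorm(400, 10, 1)), c(2, 400, 1))
  b <- aperm(array(c(rnorm(400, 0, 1), rnorm(400, 10, 1)), c(400, 2, 1)),
             c(2, 1, 3))
  dimnames(b) <- list(NULL, NULL, "p")
  expect_gt(rhat(b)[["p"]], 3)
  # hand-computable two-chain example, split halves of length 2
  x <- array(c(1, 5, 2, 6, 3, 7, 4, 8), c(2, 4, 1),
             dimnames = list(NULL, NULL, "p"))
  segs <- list(c(1, 2), c(5, 6), c(3, 4), c(7, 8))
  W <- mean(vapply(segs, var, 1))
  B <- 2 * var(vapply(segs, mean, 1))
  manual <- sqrt(((2 - 1) / 2 * W + B / 2) / W)
  expect_equal(rhat(x)[["p"]], manual, tolerance = 1e-10)
  expect_error(rhat(x[1, , , drop = FALSE]), "2 chains")
})

test_that("WAIC matches hand computation and its degenerate limits", {
  # all draws identical: no effective parameters
  ll <- matrix(rep(c(-1.3, -0.7, -2.1), each = 4), nrow = 4)
  w <- waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * sum(ll[1, ]), tolerance = 1e-12)
  # single trial, two draws, worked by hand
  ll2 <- matrix(c(-1, -2), ncol = 1)
  w2 <- waic(ll2)
  lppd <- log((exp(-1) + exp(-2)) / 2)
  expect_equal(w2$waic, -2 * (lppd - var(c(-1, -2))), tolerance = 1e-12)
  expect_equal(w2$pointwise, w2$waic)
  expect_error(waic(matrix(c(1, NA), ncol = 1)), "finite")
  # invariance to draw order / chain relabeling
  set.seed(3)
  ll3 <- matrix(rnorm(200, -1), 20, 10)
  expect_equal(waic(ll3)$waic, waic(ll3[sample(20), ])$waic,
               tolerance = 1e-12)
})

test_that("WAIC comparison computes differences, SEs and guarded effects", {
  set.seed(4)
  ll <- matrix(rnorm(300, -1, 0.3), 10, 30)
  wa <- waic(ll)
  same <- compare_waic(wa, waic(ll))
  expect_equal(same$waic_difference, 0)
  expect_equal(same$standardized_effect, 0)
  # constant per-trial log-likelihood shift: closed-form difference, zero SE
  cc <- 0.25
  wb <- waic(ll + cc)
  cmp <- compare_waic(wa, wb)
  expect_equal(cmp$waic_difference, 2 * 30 * cc, tolerance = 1e-9)
  expect_lt(cmp$se_of_difference, 1e-9)
  # SE collapses to (numerically) zero; the effect is guarded as extreme
  expect_true(is.infinite(cmp$standardized_effect) ||
                abs(cmp$standardized_effect) > 1e6)
  # internal consistency of the standardized effect
  wc <- waic(ll + matrix(rnorm(300, 0, 0.1), 10, 30))
  cmp2 <- compare_waic(wa, wc)
  expect_equal(cmp2$standardized_effect,
               cmp2$waic_difference / cmp2$se_of_difference,
               tolerance = 1e-10)
  expect_error(compare_waic(wa, waic(ll[, 1:10])), "different numbers")
})

test_that("posterior ranks are uniform when fitting data from the prior", {
  # simulation-based calibration of the quadratic-RT sampler at small scale
  n_subj <- 5; n_trials <- 15; reps <- 200
  ranks <- integer(reps)
  L <- 24 # kept draws per fit after thinning
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    mu <- rnorm(3); sg <- abs(rnorm(3)); sde <- abs(rnorm(1))
    trials <- do.call(rbind, lapply(seq_len(n_subj), function(s) {
      b <- rnorm(3, mu, sg)
      x <- rnorm(n_trials)
      data.frame(participant = s, v_rem = x,
                 rt_logz = rnorm(n_trials, b[1] + b[2] * (x + b[3])^2, sde),
                 v_left = 0, v_right = x, rem_left = 0L, rem_right = 1L,
                 response = "right", rt_s = 1)
    }))
    cfg <- suppressWarnings(sampler_config(n_chains = 1, n_iter = 480,
                                           seed = 2000 + r, thin = 10))
    fit <- sample_posterior(rt_quadratic_model(), trials, cfg,
                            store_loglik = FALSE)
    x <- extract_draws(fit, "mu_b2")[seq_len(L)]
    ranks[r] <- sum(x < mu[3])
  }
  # chi-square uniformity over rank bins
  bins <- table(factor(ranks %/% 5, levels = 0:4))
  p <- suppressWarnings(chisq.test(bins)$p.value)
  expect_gt(p, 0.01)
})
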