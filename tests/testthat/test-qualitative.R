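# Qualitative battery: RT-curve shift, Savage-Dickey factor, choice bias,
# bias correlation.

make_quad_trials <- function(n_subj, n_trials, beta, noise = 0.05,
                             beta_sd = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_subj), function(s) {
    b <- rnorm(3, beta, beta_sd)
    x <- runif(n_trials, -2, 2)
    data.frame(participant = s, v_rem = x,
               rt_logz = rnorm(n_trials, b[1] + b[2] * (x + b[3])^2, noise),
               v_left = 0, v_right = x, rem_left = 0L, rem_right = 1L,
               response = "right", rt_s = 1)
  }))
}

test_that("the quadratic RT model recovers generating betas and their vertex", {
  trials <- make_quad_trials(12, 40, c(0.5, -0.2, 0.7))
  fit <- fit_rt_quadratic(trials, quick_config(seed = 2, n_iter = 2000))
  for (i in 1:3) {
    h <- hdi(extract_draws(fit, paste0("mu_b", i - 1)))
    expect_gt(c(0.5, -0.2, 0.7)[i], h[["lower"]])
    expect_lt(c(0.5, -0.2, 0.7)[i], h[["upper"]])
  }
  # the fitted curve's extremum sits at v_rem = -b2
  b <- colMeans(do.call(cbind, lapply(0:2, function(i)
    extract_draws(fit, paste0("mu_b", i)))))
  curve_fn <- function(v) b[1] + b[2] * (v + b[3])^2
  opt <- optimize(curve_fn, c(-2, 2), maximum = b[2] < 0)
  expect_equal(opt[[1]], -b[3], tolerance = 1e-6)
})

test_that("RT data symmetric about zero yield a shift straddling zero", {
  trials <- make_quad_trials(12, 40, c(0.2, -0.15, 0), noise = 0.3,
                             beta_sd = c(0.1, 0.05, 0.1), seed = 5)
  fit <- fit_rt_quadratic(trials, quick_config(seed = 2, n_iter = 2000))
  h <- hdi(extract_draws(fit, "mu_b2"))
  expect_lt(h[["lower"]], 0)
  expect_gt(h[["upper"]], 0)
})

test_that("Savage-Dickey ratio behaves at its calibration points", {
  set.seed(11)
  # no updating: posterior equals the prior, BF near 1
  bf1 <- savage_dickey_bf(rnorm(1e5))
  expect_lt(abs(bf1$bf10 - 1), 0.1)
  # posterior mass far from zero: strong evidence
  bf2 <- savage_dickey_bf(rnorm(1e5, 3, 0.3))
  expect_gt(bf2$bf10, 100)
  expect_true(is.finite(bf2$bf10))
  # conjugate closed form within 10% at 1e5 samples
  post_m <- 0.6; post_s <- 0.4
  bf3 <- savage_dickey_bf(rnorm(1e5, post_m, post_s))
  analytic <- dnorm(0) / dnorm(0, post_m, post_s)
  expect_lt(abs(bf3$bf10 - analytic) / analytic, 0.1)
  expect_warning(savage_dickey_bf(rnorm(100)), "1000")
})

test_that("the choice-bias model recovers, negates under recoding, and nulls", {
  set.seed(21)
  n_subj <- 20; n_trials <- 80
  trials <- do.call(rbind, lapply(seq_len(n_subj), function(s) {
    icpt <- rnorm(1, 0.35, 0.2); slope <- rnorm(1, 1, 0.2)
    x <- runif(n_trials, -2, 2)
    rem_right <- rbinom(n_trials, 1L, 0.5)
    chose_rem <- rbinom(n_trials, 1L, plogis(icpt + slope * x))
    data.frame(participant = s, v_left = ifelse(rem_right == 1, 0, x),
               v_right = ifelse(rem_right == 1, x, 0),
               rem_left = 1L - rem_right, rem_right = rem_right,
               response = ifelse(chose_rem == (rem_right == 1), "right", "left"),
               rt_s = 1)
  }))
  fit <- fit_choice_logistic(trials, quick_config(seed = 3, n_iter = 2500))
  h <- hdi(extract_draws(fit, "mu_intercept"))
  expect_gt(0.35, h[["lower"]]); expect_lt(0.35, h[["upper"]])
  expect_gt(h[["lower"]], 0)
  # recoding the outcome as "chose the forgotten option" negates the bias
  flipped <- trials
  flipped[c("rem_left", "rem_right")] <- trials[c("rem_right", "rem_left")]
  flipped[c("v_left", "v_right")] <- trials[c("v_right", "v_left")]
  fit2 <- fit_choice_logistic(flipped, quick_config(seed = 3, n_iter = 2500))
  m1 <- mean(extract_draws(fit, "mu_intercept"))
  m2 <- mean(extract_draws(fit2, "mu_intercept"))
  expect_lt(abs(m1 + m2), 0.1)
  # perfectly balanced choices: intercept straddles zero
  bal <- trials[rep(seq_len(nrow(trials)), 2), ]
  half <- seq_len(nrow(trials))
  bal$response[half] <- "right"; bal$response[-half] <- "left"
  fit3 <- fit_choice_logistic(bal, quick_config(seed = 3, n_iter = 2000))
  h3 <- hdi(extract_draws(fit3, "mu_intercept"))
  expect_lt(h3[["lower"]], 0); expect_gt(h3[["upper"]], 0)
  expect_error(fit_choice_logistic(trials[0, ]), "no trials")
})

test_that("the Bayesian correlation is calibrated at its reference points", {
  set.seed(31)
  # identical vectors: correlation concentrated near one
  x <- rnorm(30)
  r1 <- correlate_bias(x, x)
  expect_gt(r1$r, 0.9)
  # independent vectors: interval straddles zero
  r2 <- correlate_bias(rnorm(90), rnorm(90))
  expect_lt(r2$hdi[["lower"]], 0); expect_gt(r2$hdi[["upper"]], 0)
  expect_error(correlate_bias(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(correlate_bias(rnorm(4), rnorm(4)))
})

test_that("the correlation interval covers a true correlation of .5", {
  set.seed(32)
  cover <- 0
  reps <- 60
  for (i in seq_len(reps)) {
    x <- rnorm(90)
    y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(90)
    r <- correlate_bias(x, y, config = sampler_config(n_chains = 2,
                                                      n_iter = 1500,
                                                      seed = i))
    cover <- cover + (r$hdi[["lower"]] <= 0.5 && 0.5 <= r$hdi[["upper"]])
  }
  expect_gte(cover / reps, 0.9)
})
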