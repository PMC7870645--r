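# SPDM and DPDM trial-level models: transformations, drift construction,
# likelihood composition.

test_that("unconstrained draws map through the documented transformations", {
  p <- transform_subject_draw(c(0, 0, log(0.3), 0, -0.5), "spdm")
  expect_equal(p$a, 1)
  expect_equal(p$z, 0.5)
  expect_equal(p$t_er, 0.3)
  expect_equal(p$d_spdm, 1)
  expect_equal(p$gamma, -0.5)
  q <- transform_subject_draw(c(0.2, 0, -1, 0.1, -0.3, 1.959964), "dpdm")
  expect_equal(q$delta, 0.975, tolerance = 1e-6)
  expect_equal(q$a, exp(0.2))
  expect_error(transform_subject_draw(c(0, 0), "spdm"))
})

test_that("SPDM drift compares the remembered value against the reference", {
  tr <- data.frame(participant = 1, v_left = -0.2, v_right = 0.3,
                   rem_left = 0L, rem_right = 1L, response = "right",
                   rt_s = 0.9)
  p <- spdm_params(1, 0.5, 0.25, 1, -0.5)
  expect_equal(spdm_drift(tr, p), 0.8)
  # indifference exactly at the reference value
  tr2 <- tr; tr2$v_right <- -0.5
  expect_equal(spdm_drift(tr2, p), 0)
  # mirrored trial flips the drift sign
  mir <- tr
  mir[c("v_left", "v_right")] <- tr[c("v_right", "v_left")]
  mir[c("rem_left", "rem_right")] <- tr[c("rem_right", "rem_left")]
  expect_equal(spdm_drift(mir, p), -0.8)
  # non-mixed trials violate the contract
  bad <- tr; bad$rem_left <- 1L
  expect_error(spdm_drift(bad, p), "mixed")
})

test_that("DPDM drifts split into a value-driven and a value-blind component", {
  tr <- data.frame(participant = 1, v_left = -0.2, v_right = 0.3,
                   rem_left = 0L, rem_right = 1L, response = "right",
                   rt_s = 0.9)
  p <- dpdm_params(1, 0.5, 0.25, 1, 0.4, 0.5)
  dv <- dpdm_drifts(tr, p)
  expect_equal(dv$utility, 0.3)
  expect_equal(dv$heuristic, 0.4)
  tl <- tr; tl$rem_left <- 1L; tl$rem_right <- 0L
  expect_equal(dpdm_drifts(tl, p)$heuristic, -0.4)
  # the heuristic ignores the values entirely
  tr3 <- tr; tr3$v_left <- 5; tr3$v_right <- -5
  expect_equal(dpdm_drifts(tr3, p)$heuristic, dv$heuristic)
})

test_that("SPDM likelihood is the Wiener density at the constructed drift", {
  trials <- make_mixed_trials(40, seed = 3)
  p <- spdm_params(0.9, 0.55, 0.25, 0.8, -0.4)
  ll <- spdm_trial_loglik(trials, p)
  v <- spdm_drift(trials, p)
  wp <- wiener_params(0, p$a, p$z, p$t_er, 1)
  direct <- fpt_log_density(trials$rt_s, trials$response == "right", wp,
                            drift = v)
  expect_identical(ll, direct)
  # joint density over (response, rt) is a proper density
  one <- trials[1, ]
  tot <- 0
  for (resp in c("left", "right")) {
    f <- Vectorize(function(t) { x <- one; x$rt_s <- t; x$response <- resp
      exp(spdm_trial_loglik(x, p)) })
    tot <- tot + integrate(f, p$t_er, Inf, rel.tol = 1e-10)$value
  }
  expect_equal(tot, 1, tolerance = 1e-6)
  expect_equal(spdm_trial_loglik(one, p, noise = 1),
               spdm_trial_loglik(one, p))
  one$rt_s <- 0.1
  expect_identical(spdm_trial_loglik(one, p), -Inf)
})

test_that("a strongly biased reference drives remembered-option choice to 1", {
  tr <- data.frame(participant = 1, v_left = 0, v_right = 0, rem_left = 0L,
                   rem_right = 1L, response = "right", rt_s = 1)
  for (g in c(-1, -5, -20)) {
    p <- spdm_params(1, 0.5, 0.2, 1, g)
    prob <- choice_probability(spdm_drift(tr, p), p$a)
    expect_gte(prob, choice_probability(-g, 1) - 1e-12)
  }
  p <- spdm_params(1, 0.5, 0.2, 1, -20)
  expect_gt(choice_probability(spdm_drift(tr, p), p$a), 1 - 1e-8)
})

test_that("DPDM mixture likelihood interpolates its components", {
  trials <- make_mixed_trials(60, seed = 4)
  base <- list(a = 0.9, z = 0.5, t_er = 0.25, d_utility = 0.8,
               d_heuristic = 0.5)
  pu <- do.call(dpdm_params, c(base, delta = 1))
  ph <- do.call(dpdm_params, c(base, delta = 0))
  pm <- do.call(dpdm_params, c(base, delta = 0.5))
  # degenerate mixtures equal the single-component Wiener densities
  wp <- wiener_params(0, base$a, base$z, base$t_er, 1)
  up <- trials$response == "right"
  dv <- dpdm_drifts(trials, pm)
  fu <- fpt_log_density(trials$rt_s, up, wp, drift = dv$utility)
  fh <- fpt_log_density(trials$rt_s, up, wp, drift = dv$heuristic)
  expect_equal(dpdm_trial_loglik(trials, pu), fu, tolerance = 1e-12)
  expect_equal(dpdm_trial_loglik(trials, ph), fh, tolerance = 1e-12)
  # an even mixture is the arithmetic mean of the component densities
  expect_equal(dpdm_trial_loglik(trials, pm),
               log(0.5 * exp(fu) + 0.5 * exp(fh)), tolerance = 1e-12)
})

test_that("relabeling left and right negates drifts and swaps densities", {
  trials <- make_mixed_trials(30, seed = 5)
  flip <- trials
  flip[c("v_left", "v_right")] <- trials[c("v_right", "v_left")]
  flip[c("rem_left", "rem_right")] <- trials[c("rem_right", "rem_left")]
  flip$response <- ifelse(trials$response == "right", "left", "right")
  ps <- spdm_params(0.9, 0.5, 0.25, 0.8, -0.4)
  expect_equal(spdm_drift(flip, ps), -spdm_drift(trials, ps))
  expect_equal(spdm_trial_loglik(flip, ps), spdm_trial_loglik(trials, ps),
               tolerance = 1e-10)
  pd <- dpdm_params(0.9, 0.5, 0.25, 0.8, 0.5, 0.6)
  dv <- dpdm_drifts(trials, pd); dvf <- dpdm_drifts(flip, pd)
  expect_equal(dvf$utility, -dv$utility)
  expect_equal(dvf$heuristic, -dv$heuristic)
  expect_equal(dpdm_trial_loglik(flip, pd), dpdm_trial_loglik(trials, pd),
               tolerance = 1e-10)
})

test_that("choice curves cross indifference at their account's reference point", {
  mk <- function(v) data.frame(participant = 1, v_left = 0, v_right = v,
                               rem_left = 0L, rem_right = 1L,
                               response = "right", rt_s = 1)
  ps <- spdm_params(1, 0.5, 0.2, 0.8, -0.6)
  expect_equal(choice_probability(spdm_drift(mk(-0.6), ps), ps$a), 0.5)
  expect_gt(choice_probability(spdm_drift(mk(0), ps), ps$a), 0.5)
  pd <- dpdm_params(1, 0.5, 0.2, 0.8, 0.5, 0.5, v_avg = 0)
  dv0 <- dpdm_drifts(mk(0), pd)
  expect_equal(choice_probability(dv0$utility, pd$a), 0.5)
  # the heuristic component is flat in the remembered value
  expect_equal(dpdm_drifts(mk(-2), pd)$heuristic,
               dpdm_drifts(mk(2), pd)$heuristic)
})

test_that("simulated RT curves peak at the account's reference point", {
  # single agent, many trials; fit the shifted quadratic by least squares
  n <- 20000
  set.seed(31)
  v_rem <- runif(n, -2, 2)
  mk <- function() data.frame(participant = 1, v_left = 0, v_right = v_rem,
                              rem_left = 0L, rem_right = 1L,
                              response = NA, rt_s = NA)
  fit_shift <- function(drift, p) {
    wp <- wiener_params(0, p$a, p$z, p$t_er, 1)
    s <- simulate_trials(wp, drift = drift, max_time = 30)
    ok <- !is.na(s$rt)
    nl <- nls(y ~ b0 + b1 * (x + b2)^2,
              data = data.frame(y = log(s$rt[ok]), x = v_rem[ok]),
              start = list(b0 = 0, b1 = -0.05, b2 = 0))
    ci <- suppressMessages(confint.default(nl))
    list(est = coef(nl)[["b2"]], ci = ci["b2", ])
  }
  # DPDM: per-trial process selection; RT curve symmetric about v_avg = 0
  pd <- dpdm_params(0.9, 0.5, 0.25, 1.1, 0.8, 0.55, v_avg = 0)
  k <- rbinom(n, 1, pd$delta)
  dv <- dpdm_drifts(mk(), pd)
  r <- fit_shift(ifelse(k == 1, dv$utility, dv$heuristic), pd)
  expect_gt(r$ci[2], 0); expect_lt(r$ci[1], 0)
  # SPDM with a negative reference: peak near gamma, shift clearly positive
  ps <- spdm_params(0.9, 0.5, 0.25, 0.6, -0.54)
  r2 <- fit_shift(spdm_drift(mk(), ps), ps)
  expect_gt(r2$ci[1], 0)
  expect_lt(abs(r2$est - 0.54), 0.25)
})
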