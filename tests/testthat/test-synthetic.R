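# Synthetic remember-and-decide generator.

test_that("trial skeletons respect the design contracts", {
  expect_error(study_design(n_participants = 0), "n_participants")
  # full memory: no mixed trials
  set.seed(1)
  sk <- generate_design_trials(study_design(5, 40, memory_accuracy = 1))
  expect_true(all(sk$rem_left + sk$rem_right == 2L))
  # memory accuracy .5: half the trials mixed, within binomial error
  set.seed(2)
  d <- study_design(20, 200, memory_accuracy = 0.5)
  sk <- generate_design_trials(d)
  frac <- mean(sk$rem_left + sk$rem_right == 1L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(sk)))
  # exact per-participant centering of the value scale
  for (p in unique(sk$participant)) {
    vals <- c(sk$v_left[sk$participant == p], sk$v_right[sk$participant == p])
    expect_lt(abs(mean(vals)), 1e-12)
  }
})

test_that("simulated behavior is reproducible and matches the choice oracle", {
  des <- study_design(8, 150, rng_seed = 5)
  s1 <- simulate_study(des, "spdm")
  s2 <- simulate_study(des, "spdm")
  expect_identical(s1, s2)
  # near-zero remembered value: remembered option still preferred, at the
  # rate the closed form predicts for drift d * (0 - gamma)
  sim <- s1
  tr <- annotate_memory(filter_trials(sim$trials)$kept)
  near0 <- abs(tr$v_rem) < 0.25
  pid <- match(tr$participant[near0], seq_along(sim$truth$subjects$params))
  pred <- vapply(seq_len(sum(near0)), function(i) {
    p <- sim$truth$subjects$params[[pid[i]]]
    choice_probability(p$d_spdm * (tr$v_rem[near0][i] - p$gamma), p$a)
  }, numeric(1))
  n0 <- sum(near0)
  expect_gt(n0, 50)
  expect_lt(abs(mean(tr$chose_rem[near0]) - mean(pred)),
            3 * sqrt(mean(pred * (1 - pred)) / n0) + 0.02)
})

test_that("DPDM generation records process indicators that behave as labeled", {
  des <- study_design(12, 160, rng_seed = 6, omission_rate = 0,
                      fast_rt_rate = 0)
  sim <- simulate_study(des, "dpdm")
  expect_false(is.null(sim$truth$process_indicators))
  expect_true(all(sim$truth$process_indicators %in% 0:1))
  spdm_sim <- simulate_study(study_design(3, 10, rng_seed = 1), "spdm")
  expect_null(spdm_sim$truth$process_indicators)
  # on heuristic trials, choosing the remembered option is independent of
  # its value: logistic slope indistinguishable from 0
  mixed <- which(sim$trials$rem_left + sim$trials$rem_right == 1L &
                   sim$trials$response != "none")
  tr <- annotate_memory(sim$trials[mixed, ])
  k <- sim$truth$process_indicators[mixed]
  expect_gt(sum(k == 0L), 400)
  g <- glm(chose_rem ~ v_rem, family = binomial(), data = tr[k == 0L, ])
  ci <- suppressMessages(confint.default(g))["v_rem", ]
  expect_lt(ci[1], 0); expect_gt(ci[2], 0)
  # and on utility trials the slope is clearly positive
  g2 <- glm(chose_rem ~ v_rem, family = binomial(), data = tr[k == 1L, ])
  expect_gt(suppressMessages(confint.default(g2))["v_rem", 1], 0)
})

test_that("contamination hits the configured rates and is fully audited", {
  base <- data.frame(participant = 1, v_left = 0, v_right = 0.5,
                     rem_left = 0L, rem_right = 1L,
                     response = "right", rt_s = 0.8)
  trials <- base[rep(1, 1e5), ]
  expect_identical(contaminate(trials, 0, 0), trials)
  set.seed(10)
  out <- contaminate(trials, 0.020, 0.014)
  p_om <- mean(out$provenance == "omission")
  p_fa <- mean(out$provenance == "fast")
  expect_lt(abs(p_om - 0.020), 3 * sqrt(0.020 * 0.980 / 1e5))
  expect_lt(abs(p_fa - 0.014 * 0.98), 3 * sqrt(0.014 * 0.986 / 1e5))
  expect_true(all(out$response[out$provenance == "omission"] == "none"))
  expect_true(all(is.na(out$rt_s[out$provenance == "omission"])))
  fast <- out$provenance == "fast"
  expect_true(all(out$rt_s[fast] > 0.05 & out$rt_s[fast] < 0.2))
})

test_that("ground truth round-trips through JSON", {
  sim <- simulate_study(study_design(5, 30, rng_seed = 9), "dpdm")
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$model_tag, "dpdm")
  expect_equal(back$group$mu, sim$truth$group$mu)
  expect_equal(back$group$sigma, sim$truth$group$sigma)
  expect_equal(unname(back$subjects$raw),
               unname(sim$truth$subjects$raw), tolerance = 1e-12)
  expect_equal(back$process_indicators, sim$truth$process_indicators)
  expect_equal(back$subjects$params[[2]]$delta,
               sim$truth$subjects$params[[2]]$delta, tolerance = 1e-12)
})

test_that("subjects drawn from a degenerate-utility group behave utility-only", {
  g <- default_ground_truth("dpdm")
  g$mu[["delta"]] <- 8; g$sigma[["delta"]] <- 1e-3
  sim <- simulate_study(study_design(6, 80, rng_seed = 7), "dpdm", group = g)
  expect_true(all(sim$truth$process_indicators == 1L))
})
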