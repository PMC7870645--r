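# shared fixtures, all generated in code

# small table of responded mixed trials with arbitrary but valid values
make_mixed_trials <- function(n = 50, seed = 1, participants = 1L) {
  set.seed(seed)
  rem_right <- rbinom(n, 1L, 0.5)
  data.frame(
    participant = rep_len(participants, n),
    v_left = rnorm(n), v_right = rnorm(n),
    rem_left = 1L - rem_right, rem_right = rem_right,
    response = sample(c("left", "right"), n, replace = TRUE),
    rt_s = 0.35 + rexp(n, 2))
}

quick_config <- function(seed = 1, n_iter = 600, n_chains = 2, thin = 1) {
  sampler_config(n_chains = n_chains, n_iter = n_iter, seed = seed,
                 thin = thin)
}

# numeric integral of the defective density at one boundary
integrate_boundary <- function(params, upper) {
  f <- Vectorize(function(t) exp(fpt_log_density(t, upper, params)))
  integrate(f, params$nondecision_time, Inf, rel.tol = 1e-10,
            abs.tol = 1e-12)$value
}
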