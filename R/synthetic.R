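# Synthetic remember-and-decide study generator. Produces trial tables with
# the same structure as the empirical task (two snack options per trial,
# per-participant centered subjective values, remembered/forgotten status,
# choices and RTs from either generating model) plus contamination
# (omissions, anticipatory fast RTs) so the preprocessing filters and every
# downstream stage can be exercised against known ground truth.

#' Synthetic study design
#'
#' @param n_participants number of participants.
#' @param n_trials_per_participant decision trials per participant (all
#'   trial types; about `2 * p * (1 - p)` of them are mixed trials at
#'   memory accuracy `p`).
#' @param value_sd standard deviation of subjective snack values
#'   (participant-mean-centered units).
#' @param memory_accuracy probability that an option is remembered.
#' @param omission_rate fraction of trials with no response (default .020,
#'   the empirical no-choice rate).
#' @param fast_rt_rate fraction of trials with anticipatory RTs below the
#'   200 ms cutoff (default .014, the empirical fast-guess rate).
#' @param rng_seed integer seed used by [simulate_study()].
#' @return object of class `study_design`.
#' @export
study_design <- function(n_participants = 30L, n_trials_per_participant = 100L,
                         value_sd = 1, memory_accuracy = 0.66,
                         omission_rate = 0.020, fast_rt_rate = 0.014,
                         rng_seed = 1L) {
  stopifnot(n_participants >= 1, n_trials_per_participant >= 1, value_sd > 0,
            memory_accuracy >= 0, memory_accuracy <= 1,
            omission_rate >= 0, omission_rate <= 1,
            fast_rt_rate >= 0, fast_rt_rate <= 1)
  structure(list(n_participants = as.integer(n_participants),
                 n_trials_per_participant = as.integer(n_trials_per_participant),
                 value_sd = value_sd, memory_accuracy = memory_accuracy,
                 omission_rate = omission_rate, fast_rt_rate = fast_rt_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "study_design")
}

#' Group-level hyperparameters
#'
#' Location/scale pairs of the normal distributions from which
#' unconstrained subject-level parameters are drawn.
#'
#' @param mu named numeric vector of group locations (raw scale).
#' @param sigma named numeric vector of positive group scales, same names.
#' @param model_tag `"spdm"` or `"dpdm"`.
#' @return object of class `group_hyperparams`.
#' @export
group_hyperparams <- function(mu, sigma, model_tag) {
  nm <- .par_names(model_tag)
  stopifnot(setequal(names(mu), nm), setequal(names(sigma), nm),
            all(sigma > 0))
  structure(list(mu = mu[nm], sigma = sigma[nm], model_tag = model_tag),
            class = "group_hyperparams")
}

#' Default generating hyperparameters
#'
#' Group-level values chosen to emulate the empirical task: non-decision
#' time around .29 s, a mild right-side start bias (z around .52), a
#' reference value gamma around -.54 value-sd units (the memory bias), and
#' a utility-process proportion delta around .55. Thresholds are ~0.9
#' evidence units on the symmetric scale (~1.8 full separation). Because
#' the empirical rating scale is unknown, the value-denominated drift
#' scalings are calibrated behaviorally instead of transplanted: d is set
#' so that a 1-sd value difference yields roughly 73-77% choice accuracy
#' (d_spdm ~ .60; d_utility ~ 1.10), and the heuristic drift (~.80, a
#' scale-free quantity) gives a clearly separated fast value-blind
#' process.
#'
#' @param model_tag `"spdm"` or `"dpdm"`.
#' @return a [group_hyperparams()] object.
#' @export
default_ground_truth <- function(model_tag = c("spdm", "dpdm")) {
  model_tag <- match.arg(model_tag)
  if (model_tag == "spdm") {
    group_hyperparams(
      mu = c(a = log(0.9), z = qnorm(0.52), t_er = log(0.29),
             d_spdm = log(0.60), gamma = -0.54),
      sigma = c(a = 0.25, z = 0.10, t_er = 0.35, d_spdm = 0.50, gamma = 0.45),
      model_tag = "spdm")
  } else {
    group_hyperparams(
      mu = c(a = log(0.9), z = qnorm(0.52), t_er = log(0.29),
             d_utility = log(1.10), d_heuristic = log(0.80),
             delta = qnorm(0.55)),
      sigma = c(a = 0.25, z = 0.10, t_er = 0.35, d_utility = 0.40,
                d_heuristic = 0.40, delta = 0.60),
      model_tag = "dpdm")
  }
}

#' Draw subject-level parameters from the group distribution
#'
#' @param group a [group_hyperparams()] object.
#' @param n_subjects number of participants.
#' @return list with `raw` (n x K matrix of unconstrained draws) and
#'   `params` (list of per-subject parameter objects).
#' @export
draw_subjects <- function(group, n_subjects) {
  stopifnot(inherits(group, "group_hyperparams"))
  nm <- names(group$mu)
  raw <- sapply(nm, function(k) rnorm(n_subjects, group$mu[[k]], group$sigma[[k]]))
  raw <- matrix(raw, nrow = n_subjects, dimnames = list(NULL, nm))
  params <- lapply(seq_len(n_subjects), function(s)
    transform_subject_draw(raw[s, ], group$model_tag))
  list(raw = raw, params = params)
}

#' Generate trial skeletons (values and memory status, no responses)
#'
#' Per participant, subjective values for both options are drawn from
#' `N(0, value_sd)` and centered to a participant mean of exactly zero;
#' remembered flags are i.i.d. Bernoulli(memory_accuracy) per option, so
#' all trial types (mixed, both-remembered, both-forgotten) occur. Memory
#' status is independent of value.
#'
#' @param design a [study_design()] object.
#' @return data.frame with columns participant, trial, v_left, v_right,
#'   rem_left, rem_right.
#' @export
generate_design_trials <- function(design) {
  stopifnot(inherits(design, "study_design"))
  nt <- design$n_trials_per_participant
  out <- lapply(seq_len(design$n_participants), function(p) {
    vals <- rnorm(2L * nt, 0, design$value_sd)
    vals <- vals - mean(vals)
    data.frame(participant = p, trial = seq_len(nt),
               v_left = vals[seq_len(nt)], v_right = vals[nt + seq_len(nt)],
               rem_left = rbinom(nt, 1L, design$memory_accuracy),
               rem_right = rbinom(nt, 1L, design$memory_accuracy))
  })
  do.call(rbind, out)
}

# generative drift for any trial type (mixed trials reduce to the
# remembered-vs-reference comparison; both-remembered trials to a plain
# value comparison; both-forgotten trials to zero drift)
.gen_drift_spdm <- function(tr, p) {
  p$d_spdm * (tr$rem_right * (tr$v_right - p$gamma) -
              tr$rem_left * (tr$v_left - p$gamma))
}
.gen_drift_dpdm_utility <- function(tr, p) {
  p$d_utility * (tr$rem_right * (tr$v_right - p$v_avg) -
                 tr$rem_left * (tr$v_left - p$v_avg))
}
.gen_drift_dpdm_heuristic <- function(tr, p) {
  p$d_heuristic * (tr$rem_right - tr$rem_left)
}

#' Simulate choices and response times for trial skeletons
#'
#' SPDM: one diffusion simulation per trial at the SPDM drift. DPDM: the
#' governing process of each trial is a Bernoulli(delta_s) draw (recorded
#' as the process indicator k; 1 = utility), and the trial is simulated at
#' the selected component drift. Timeouts become omitted responses.
#'
#' @param skeletons output of [generate_design_trials()].
#' @param truth list with elements `model_tag`, `group`
#'   ([group_hyperparams()]) and `subjects` (output of [draw_subjects()]).
#' @param time_step,max_time simulator settings (seconds).
#' @return list with `trials` (completed data.frame: response, rt_s,
#'   provenance) and `truth` (input truth, with `process_indicators` added
#'   for DPDM data).
#' @export
simulate_behavior <- function(skeletons, truth, time_step = 1e-3, max_time = 10) {
  stopifnot(truth$model_tag %in% c("spdm", "dpdm"))
  n_subj <- length(truth$subjects$params)
  if (n_subj != length(unique(skeletons$participant)))
    stop("skeletons and truth must describe the same participants")
  trials <- skeletons
  trials$response <- NA_character_
  trials$rt_s <- NA_real_
  kvec <- rep(NA_integer_, nrow(trials))
  for (s in seq_len(n_subj)) {
    idx <- which(trials$participant == s)
    p <- truth$subjects$params[[s]]
    if (truth$model_tag == "spdm") {
      v <- .gen_drift_spdm(trials[idx, ], p)
    } else {
      k <- rbinom(length(idx), 1L, p$delta)
      kvec[idx] <- k
      v <- ifelse(k == 1L, .gen_drift_dpdm_utility(trials[idx, ], p),
                  .gen_drift_dpdm_heuristic(trials[idx, ], p))
    }
    wp <- wiener_params(0, p$a, p$z, p$t_er, 1)
    sim <- simulate_trials(wp, drift = v, time_step = time_step,
                           max_time = max_time)
    trials$response[idx] <- ifelse(is.na(sim$hit_upper), "none",
                                   ifelse(sim$hit_upper, "right", "left"))
    trials$rt_s[idx] <- sim$rt
  }
  trials$provenance <- ifelse(trials$response == "none", "timeout", "clean")
  if (truth$model_tag == "dpdm") truth$process_indicators <- kvec
  list(trials = trials, truth = truth)
}

#' Inject contamination into a simulated trial table
#'
#' Randomly selected trials become omissions (`response = "none"`, RT
#' absent) or anticipatory fast guesses (RT uniform on (0.05, 0.2) s with a
#' random response). Contaminated trials are flagged in the `provenance`
#' column so the exclusion filters can be audited.
#'
#' @param trials completed trial data.frame.
#' @param omission_rate,fast_rt_rate contamination probabilities.
#' @return the trial data.frame with contamination applied.
#' @export
contaminate <- function(trials, omission_rate = 0.020, fast_rt_rate = 0.014) {
  stopifnot(omission_rate >= 0, omission_rate <= 1,
            fast_rt_rate >= 0, fast_rt_rate <= 1)
  if (omission_rate == 0 && fast_rt_rate == 0) return(trials)
  n <- nrow(trials)
  if (!"provenance" %in% names(trials)) trials$provenance <- "clean"
  om <- runif(n) < omission_rate
  fa <- !om & runif(n) < fast_rt_rate
  trials$response[om] <- "none"
  trials$rt_s[om] <- NA_real_
  trials$provenance[om] <- "omission"
  nf <- sum(fa)
  if (nf > 0) {
    trials$rt_s[fa] <- runif(nf, 0.05, 0.2)
    trials$response[fa] <- sample(c("left", "right"), nf, replace = TRUE)
    trials$provenance[fa] <- "fast"
  }
  trials
}

#' Write and read generating ground truth as JSON
#'
#' Serializes a ground-truth object (generating model, group-level
#' hyperparameters, unconstrained subject-level draws and, for DPDM data,
#' the per-trial process indicators) so a simulated study can be archived
#' next to its trial table.
#'
#' @param truth the `truth` element returned by [simulate_study()].
#' @param path JSON file path.
#' @return `path`, invisibly (`read_ground_truth` returns the truth list).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(truth$model_tag %in% c("spdm", "dpdm"))
  out <- list(model_tag = truth$model_tag,
              group = list(mu = as.list(truth$group$mu),
                           sigma = as.list(truth$group$sigma)),
              subjects_raw = apply(truth$subjects$raw, 1, as.list),
              process_indicators = truth$process_indicators)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  group <- group_hyperparams(unlist(x$group$mu), unlist(x$group$sigma),
                             x$model_tag)
  raw <- as.matrix(x$subjects_raw)
  params <- lapply(seq_len(nrow(raw)), function(s)
    transform_subject_draw(raw[s, names(group$mu)], x$model_tag))
  list(model_tag = x$model_tag, group = group,
       subjects = list(raw = raw, params = params),
       process_indicators = x$process_indicators)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: draws subjects from the group distribution (unless
#' `truth` is supplied), generates trial skeletons, simulates behavior from
#' the generating model and applies contamination. Fully reproducible from
#' `design$rng_seed`.
#'
#' @param design a [study_design()] object.
#' @param model_tag generating model, `"spdm"` or `"dpdm"`.
#' @param group generating [group_hyperparams()] (defaults to
#'   [default_ground_truth()]).
#' @param time_step,max_time simulator settings.
#' @return list with `trials` and `truth` (model_tag, group, subjects, and
#'   process_indicators for DPDM data).
#' @export
simulate_study <- function(design = study_design(),
                           model_tag = c("spdm", "dpdm"),
                           group = NULL, time_step = 1e-3, max_time = 10) {
  model_tag <- match.arg(model_tag)
  if (is.null(group)) group <- default_ground_truth(model_tag)
  stopifnot(group$model_tag == model_tag)
  set.seed(design$rng_seed)
  subjects <- draw_subjects(group, design$n_participants)
  skel <- generate_design_trials(design)
  truth <- list(model_tag = model_tag, group = group, subjects = subjects)
  sim <- simulate_behavior(skel, truth, time_step = time_step,
                           max_time = max_time)
  sim$trials <- contaminate(sim$trials, design$omission_rate,
                            design$fast_rt_rate)
  sim
}
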