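# Ingestion, preprocessing and the end-to-end pipeline. The on-disk trial
# schema is a delimited table with header
#   participant, v_left, v_right, rem_left, rem_right, response, rt_s
# where response is "left"/"right"/"none" and rt_s is empty for omissions.

.trial_schema <- c("participant", "v_left", "v_right", "rem_left",
                   "rem_right", "response", "rt_s")

#' Write a trial table
#'
#' @param trials trial data.frame (extra columns such as `provenance` are
#'   preserved).
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_trials <- function(trials, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  miss <- setdiff(.trial_schema, names(trials))
  if (length(miss)) stop("trials lack required columns: ", paste(miss, collapse = ", "))
  utils::write.table(trials, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a trial table
#'
#' Enforces the documented schema: all required columns present, numeric
#' values where expected, remembered flags in \{0, 1\}, responses among
#' left/right/none, and a positive RT whenever a response was made.
#' Omissions (`response = "none"`) may have an empty RT field. Malformed
#' rows are reported with their line numbers.
#'
#' @param path file to read.
#' @param format `"csv"` or `"tsv"`.
#' @return typed trial data.frame.
#' @export
read_trials <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE,
                           sep = if (format == "csv") "," else "\t",
                           stringsAsFactors = FALSE, na.strings = "")
  miss <- setdiff(.trial_schema, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  rows <- function(cond) which(cond) + 1L # header occupies line 1
  for (col in c("v_left", "v_right", "rem_left", "rem_right", "rt_s")) {
    vals <- raw[[col]]
    bad <- !is.na(vals) & is.na(suppressWarnings(as.numeric(vals)))
    if (any(bad))
      stop("non-numeric ", col, " at line(s): ",
           paste(head(rows(bad), 5), collapse = ", "))
    raw[[col]] <- as.numeric(vals)
  }
  bad <- !(raw$rem_left %in% c(0, 1)) | !(raw$rem_right %in% c(0, 1))
  if (any(bad))
    stop("remembered flags must be 0/1; offending line(s): ",
         paste(head(rows(bad), 5), collapse = ", "))
  bad <- !(raw$response %in% c("left", "right", "none"))
  if (any(bad))
    stop("response must be left/right/none; offending line(s): ",
         paste(head(rows(bad), 5), collapse = ", "))
  responded <- raw$response != "none"
  bad <- responded & (is.na(raw$rt_s) | raw$rt_s <= 0)
  if (any(bad))
    stop("responded trials need rt_s > 0; offending line(s): ",
         paste(head(rows(bad), 5), collapse = ", "))
  raw$rem_left <- as.integer(raw$rem_left)
  raw$rem_right <- as.integer(raw$rem_right)
  raw
}

#' Apply the preprocessing exclusion filters
#'
#' Drops, in this fixed order: (1) trials with no response, (2) trials with
#' RT below 200 ms (strict `<`, unlikely to come from a deliberate
#' process), (3) trials that are not mixed trials (both accounts make
#' identical predictions when both options are remembered or both are
#' forgotten, so only one-remembered/one-forgotten trials are analyzed).
#'
#' @param trials typed trial data.frame.
#' @return list with `kept` (filtered data.frame) and `report` (an
#'   `exclusion_report`: category counts and per-participant kept counts).
#' @export
filter_trials <- function(trials) {
  n_total <- nrow(trials)
  no_choice <- trials$response == "none"
  t1 <- trials[!no_choice, , drop = FALSE]
  fast <- t1$rt_s < 0.200
  t2 <- t1[!fast, , drop = FALSE]
  wrong_type <- t2$rem_left + t2$rem_right != 1L
  kept <- t2[!wrong_type, , drop = FALSE]
  per_part <- table(factor(kept$participant,
                           levels = sort(unique(trials$participant))))
  report <- structure(list(
    n_total = n_total, n_no_choice = sum(no_choice), n_fast = sum(fast),
    n_wrong_trial_type = sum(wrong_type), n_kept = nrow(kept),
    per_participant_kept = as.integer(per_part)), class = "exclusion_report")
  stopifnot(report$n_kept == n_total - report$n_no_choice - report$n_fast -
              report$n_wrong_trial_type)
  list(kept = kept, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  cat(sprintf("  total trials      %6d\n", x$n_total))
  cat(sprintf("  no choice         %6d (%.1f%%)\n", x$n_no_choice,
              100 * x$n_no_choice / x$n_total))
  cat(sprintf("  RT < 200 ms       %6d (%.1f%%)\n", x$n_fast,
              100 * x$n_fast / x$n_total))
  cat(sprintf("  wrong trial type  %6d (%.1f%%)\n", x$n_wrong_trial_type,
              100 * x$n_wrong_trial_type / x$n_total))
  cat(sprintf("  analyzed          %6d (mean %.1f per participant)\n",
              x$n_kept, mean(x$per_participant_kept)))
  invisible(x)
}

#' Log-transform and z-standardize response times
#'
#' Adds an `rt_logz` column: natural log of the RT, then centered and
#' scaled to unit (population) variance within the chosen grouping.
#' Original RTs are preserved.
#'
#' @param trials filtered trials (all RTs positive).
#' @param grouping `"participant"` (default; the downstream regressions
#'   are hierarchical) or `"pooled"`.
#' @return trials with `rt_logz` added; also adds `v_rem`, the value of the
#'   remembered option, if missing.
#' @export
standardize_rts <- function(trials, grouping = c("participant", "pooled")) {
  grouping <- match.arg(grouping)
  if (any(is.na(trials$rt_s) | trials$rt_s <= 0))
    stop("standardize_rts requires positive RTs on every trial")
  lrt <- log(trials$rt_s)
  zfun <- function(x) {
    if (length(x) < 2L) stop("a standardization group has fewer than 2 trials")
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) stop("a standardization group has zero RT variance")
    (x - mean(x)) / s
  }
  if (grouping == "pooled") {
    trials$rt_logz <- zfun(lrt)
  } else {
    trials$rt_logz <- stats::ave(lrt, trials$participant, FUN = zfun)
  }
  if (!"v_rem" %in% names(trials))
    trials$v_rem <- ifelse(trials$rem_right == 1L, trials$v_right, trials$v_left)
  trials
}

#' Value of the remembered option and remembered-choice indicator
#'
#' Helper for mixed trials: `v_rem` is the remembered option's value,
#' `mem_side` is +1/-1 for remembered-right/left, and `chose_rem`
#' indicates whether the remembered option was chosen.
#'
#' @param trials mixed-trial data.frame.
#' @return trials with `v_rem`, `mem_side`, `chose_rem` columns.
#' @export
annotate_memory <- function(trials) {
  .check_mixed(trials)
  trials$v_rem <- ifelse(trials$rem_right == 1L, trials$v_right, trials$v_left)
  trials$mem_side <- ifelse(trials$rem_right == 1L, 1, -1)
  trials$chose_rem <- as.integer(
    (trials$response == "right") == (trials$rem_right == 1L))
  trials
}

#' Run the end-to-end analysis pipeline
#'
#' Stages: simulate (or ingest) -> preprocess -> qualitative RT/choice
#' analyses -> hierarchical diffusion-model fits -> WAIC comparison ->
#' posterior predictive checks. All artifacts are written below `out_dir`;
#' a JSON log records the seed, stage timings and exclusion counts.
#'
#' @param config named list (or path to a YAML/JSON file) with entries:
#'   `seed`; either `trials_file` or a `synthetic` block (fields of
#'   [study_design()] plus `model_tag`); `stages` (subset of
#'   `c("qualitative", "ddm", "ppc")`); `sampler` (fields of
#'   [sampler_config()]); `ppc_replicates`.
#' @param out_dir output directory (created; default a timestamped folder
#'   under `tempdir()`).
#' @return (invisibly) a list with all stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("[.]ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- if (is.null(config$stages)) c("qualitative", "ddm", "ppc") else config$stages
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(), format(Sys.time(), "memddm_%Y%m%d_%H%M%S"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config, out_dir = out_dir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  # --- data ---
  dat <- stage("data", {
    if (!is.null(config$trials_file)) {
      list(trials = read_trials(
        config$trials_file,
        format = if (grepl("[.]tsv$", config$trials_file)) "tsv" else "csv"),
        truth = NULL)
    } else {
      syn <- config$synthetic
      if (is.null(syn)) stop("config needs either trials_file or a synthetic block")
      des <- study_design(
        n_participants = syn$n_participants %||% 30L,
        n_trials_per_participant = syn$n_trials_per_participant %||% 100L,
        value_sd = syn$value_sd %||% 1,
        memory_accuracy = syn$memory_accuracy %||% 0.66,
        omission_rate = syn$omission_rate %||% 0.020,
        fast_rt_rate = syn$fast_rt_rate %||% 0.014,
        rng_seed = seed)
      sim <- simulate_study(des, model_tag = syn$model_tag %||% "spdm")
      write_trials(sim$trials, file.path(out_dir, "trials.csv"))
      list(trials = sim$trials, truth = sim$truth)
    }
  })
  res$trials_raw <- dat$trials
  res$truth <- dat$truth
  # --- preprocessing ---
  pre <- stage("preprocess", {
    f <- filter_trials(res$trials_raw)
    f$kept <- standardize_rts(annotate_memory(f$kept))
    f
  })
  res$report <- pre$report
  res$trials <- pre$kept
  utils::write.csv(data.frame(category = c("total", "no_choice", "fast",
                                           "wrong_trial_type", "kept"),
                              n = c(pre$report$n_total, pre$report$n_no_choice,
                                    pre$report$n_fast,
                                    pre$report$n_wrong_trial_type,
                                    pre$report$n_kept)),
                   file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  sc <- do.call(sampler_config, c(list(seed = seed), config$sampler))
  # --- qualitative battery ---
  if ("qualitative" %in% stages) {
    res$qualitative <- stage("qualitative",
                             qualitative_battery(res$trials, config = sc))
    q <- res$qualitative
    utils::write.csv(q$summary, file.path(out_dir, "qualitative_summary.csv"),
                     row.names = FALSE)
  }
  # --- quantitative fits + comparison ---
  if ("ddm" %in% stages) {
    res$fit_spdm <- stage("fit_spdm",
                          sample_posterior(spdm_model(), res$trials, sc))
    res$fit_dpdm <- stage("fit_dpdm",
                          sample_posterior(dpdm_model(), res$trials, sc))
    res$comparison <- stage("compare", {
      wa <- waic(pointwise_loglik(res$fit_spdm))
      wb <- waic(pointwise_loglik(res$fit_dpdm))
      compare_waic(wa, wb, labels = c("spdm", "dpdm"))
    })
    for (m in c("spdm", "dpdm")) {
      s <- summary(res[[paste0("fit_", m)]], group_only = TRUE)
      utils::write.csv(s, file.path(out_dir, paste0("fit_", m, "_group.csv")),
                       row.names = FALSE)
    }
    utils::write.csv(as.data.frame(unclass(res$comparison)[c(
      "waic_a", "waic_b", "waic_difference", "se_of_difference",
      "standardized_effect")]),
      file.path(out_dir, "model_comparison.csv"), row.names = FALSE)
  }
  # --- posterior predictive checks ---
  if ("ppc" %in% stages && !is.null(res$fit_spdm)) {
    nrep <- config$ppc_replicates %||% 200L
    res$ppc <- stage("ppc", list(
      spdm = posterior_predictive(res$fit_spdm, res$trials, n_replicates = nrep),
      dpdm = posterior_predictive(res$fit_dpdm, res$trials, n_replicates = nrep)))
    for (m in c("spdm", "dpdm"))
      utils::write.csv(res$ppc[[m]]$bins,
                       file.path(out_dir, paste0("ppc_", m, ".csv")),
                       row.names = FALSE)
  }
  log <- list(seed = seed, stages = stages,
              package_version = as.character(utils::packageVersion("memddm")),
              n_kept = res$report$n_kept, timestamp = format(Sys.time()))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
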