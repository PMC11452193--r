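# Readers/writers for the long-format choice table, cohort configs, and
# the end-to-end pipeline driver. The single interchange format is
# comma-delimited text.

CHOICE_COLUMNS <- c("participant_id", "group", "age", "mvc", "trial_index",
                    "reward_apples", "effort_frac", "accepted",
                    "exertion_required", "success", "decision_rt")

#' Write a choice-record table
#'
#' @param records long choice-record data frame (one row per trial).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_choice_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read and validate a choice-record table
#'
#' Validates every row against the choice-record invariants and reports
#' all offending rows (not just the first): reward must be 3/6/9/12,
#' effort 0.2/0.4/0.6/0.8, and a refused trial can never require
#' exertion.
#'
#' @param path CSV file with the documented columns (`participant_id`,
#'   `reward_apples`, `effort_frac`, `accepted` required; `group`,
#'   `age`, `mvc`, `trial_index`, `exertion_required`, `success`,
#'   `decision_rt` optional).
#' @return Validated records with a `row_number` column attached.
#' @export
read_choice_table <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "reward_apples", "effort_frac", "accepted")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_invalid("missing required column(s): %s", paste(miss, collapse = ", "))
  for (cc in c("accepted", "exertion_required", "success"))
    if (cc %in% names(d) && !is.logical(d[[cc]]))
      d[[cc]] <- as.logical(d[[cc]])
  d$row_number <- seq_len(nrow(d))
  probs <- character(0)
  bad_r <- which(!d$reward_apples %in% REWARD_LEVELS)
  if (length(bad_r))
    probs <- c(probs, sprintf("row %d: reward_apples=%s not in {3,6,9,12}",
                              bad_r, d$reward_apples[bad_r]))
  ok_e <- vapply(d$effort_frac, function(e)
    is.finite(e) && any(abs(e - EFFORT_LEVELS) < 1e-9), logical(1))
  if (any(!ok_e))
    probs <- c(probs, sprintf("row %d: effort_frac=%s not in {0.2,0.4,0.6,0.8}",
                              which(!ok_e), d$effort_frac[!ok_e]))
  if (any(is.na(d$accepted)))
    probs <- c(probs, sprintf("row %d: accepted missing",
                              which(is.na(d$accepted))))
  if ("exertion_required" %in% names(d)) {
    bad_x <- which(!is.na(d$accepted) & !d$accepted &
                     !is.na(d$exertion_required) & d$exertion_required)
    if (length(bad_x))
      probs <- c(probs,
                 sprintf("row %d: refused trial flagged exertion_required",
                         bad_x))
  }
  if (length(probs))
    stop_invalid("invalid choice table (%d problem rows):\n%s",
                 length(probs), paste(probs, collapse = "\n"))
  d
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates: simulate cohort -> symptom factors -> model-agnostic
#' statistics (RM-ANOVA, planned contrasts, design power) -> fit the
#' Case-control winning model with per-group priors on the parameter of
#' interest -> contrasts on the fitted acceptance bias -> a reduced
#' parameter-recovery check. All outputs are written as delimited text
#' under `out_dir`, together with a JSON manifest carrying the seed and
#' the config hash; identical configs give identical manifests.
#'
#' @param config list (or path to a JSON file) with entries `seed`
#'   (integer), `out_dir` (directory), and optionally `study`
#'   ("case_control"/"pilot"), `method` ("map"/"mcmc"),
#'   `param_of_interest` (default "K"), `recovery_n` (default 30),
#'   `n_scale` (scales group sizes down for quick demos).
#' @param verbose log stage progress?
#' @return List of stage results (cohort, anova, contrasts, power, fit,
#'   parameter contrast, recovery, manifest), invisibly.
#' @export
run_agt_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  if (is.null(config$seed) || is.null(config$out_dir))
    stop_invalid("config needs 'seed' and 'out_dir'")
  seed <- as.integer(config$seed)
  study <- config$study %||% "case_control"
  method <- config$method %||% "map"
  poi <- config$param_of_interest %||% "K"
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  manifest <- list(seed = seed, study = study, method = method,
                   package_version = as.character(utils::packageVersion("agtfit")),
                   outputs = character(0))
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config[order(names(config))], cfg_file,
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE, quote = FALSE, na = "")
    manifest$outputs <<- c(manifest$outputs, name)
    path
  }

  specs <- default_cohort(study)
  if (!is.null(config$n_scale)) {
    for (k in seq_along(specs))
      specs[[k]]$n <- as.integer(ceiling(specs[[k]]$n * config$n_scale))
  }
  if (any(vapply(specs, `[[`, integer(1), "n") < 2))
    stop_invalid("cohort config yields groups with fewer than 2 participants")

  t0 <- proc.time()[3]
  coh <- simulate_cohort(specs, seed = seed)
  say("simulate", "%d participants, %d records (%.1fs)",
      nrow(coh$truth), nrow(coh$records), proc.time()[3] - t0)
  emit(coh$records, "choices.csv")
  emit(coh$truth, "truth.csv")
  factors <- simulate_symptom_factors(coh$truth, seed = child_seed(seed, 2L))
  emit(factors, "symptom_factors.csv")

  t0 <- proc.time()[3]
  multi_group <- length(unique(coh$truth$group)) > 1
  an <- rm_anova(coh$records,
                 covariate = if (multi_group) "age" else NULL)
  say("stats", "RM-ANOVA on %d participants (%.1fs)", an$n,
      proc.time()[3] - t0)
  emit(an$table, "anova.csv")

  contrast_rows <- NULL
  if (multi_group) {
    v <- arcsine_transform(coh$truth$acceptance_rate)
    c1 <- planned_contrast(v, coh$truth$group, c("MDD", "REM"),
                           c("REL", "CTR"), covariate = coh$truth$age)
    c2 <- planned_contrast(v, coh$truth$group, c("MDD", "REM", "REL"),
                           "CTR", covariate = coh$truth$age)
    contrast_rows <- data.frame(
      contrast = c("MDD+REM vs REL+CTR", "MDD+REM+REL vs CTR"),
      scale = "arcsine acceptance",
      d = c(c1$d, c2$d), F = c(c1$F, c2$F), p = c(c1$p, c2$p))
  }
  pw <- anova_power(0.25, vapply(specs, `[[`, integer(1), "n"))
  emit(data.frame(f = 0.25, alpha = 0.05,
                  n = paste(vapply(specs, `[[`, integer(1), "n"),
                            collapse = "+"), power = pw), "power.csv")

  t0 <- proc.time()[3]
  model <- winning_model(if (study == "pilot") "pilot" else "case_control")
  fit <- fit_agt(coh$records, model = model,
                 scheme = if (multi_group) "per_group" else "shared",
                 param_of_interest = if (multi_group) poi else NULL,
                 method = method, seed = child_seed(seed, 3L))
  say("fit", "'%s' via %s (%.1fs)", model$name, method,
      proc.time()[3] - t0)
  sm <- summary(fit)
  emit(sm$participants, "fit_participants.csv")
  emit(sm$hyper, "fit_hyper.csv")

  if (multi_group && poi %in% model$free_params) {
    kv <- fit$theta_mean[, poi]
    ck <- planned_contrast(kv, fit$participants$group, c("MDD", "REM"),
                           c("REL", "CTR"), covariate = coh$truth$age)
    contrast_rows <- rbind(contrast_rows, data.frame(
      contrast = "MDD+REM vs REL+CTR", scale = paste("parameter", poi),
      d = ck$d, F = ck$F, p = ck$p))
  }
  if (!is.null(contrast_rows)) emit(contrast_rows, "contrasts.csv")

  ppc <- posterior_predictive_acceptance(fit)
  emit(ppc$participant, "ppc_participants.csv")

  t0 <- proc.time()[3]
  rec_n <- as.integer(config$recovery_n %||% 30L)
  recov <- run_recovery(model, n_participants = rec_n,
                        seed = child_seed(seed, 4L), method = method)
  say("recover", "n=%d (%.1fs)", rec_n, proc.time()[3] - t0)
  emit(recov$table, "recovery.csv")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = coh, anova = an, contrasts = contrast_rows,
                 power = pw, fit = fit, ppc = ppc, recovery = recov,
                 manifest = manifest))
}
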