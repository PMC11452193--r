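# Model comparison via importance-sampling leave-one-out predictive
# density, posterior-predictive checks, and parameter-recovery studies.

# elpd_loo from a pointwise log-likelihood matrix (draws x trials),
# with Ionides-style weight truncation at sqrt(S) * mean weight.
tis_loo <- function(ll) {
  S <- nrow(ll)
  elpd_i <- vapply(seq_len(ncol(ll)), function(i) {
    lli <- ll[, i]
    lw <- -lli                      # raw LOO weights 1 / p(y_i | theta_s)
    lw <- lw - max(lw)
    w <- exp(lw)
    w <- pmin(w, mean(w) * sqrt(S)) # truncate heavy tails
    log(sum(w * exp(lli - max(lli)))) + max(lli) - log(sum(w))
  }, numeric(1))
  list(elpd = sum(elpd_i), pointwise = elpd_i,
       se = sqrt(length(elpd_i) * stats::var(elpd_i)))
}

#' Compare fitted models by LOO predictive density
#'
#' Ranks fits of different models to the identical dataset by the
#' expected log pointwise predictive density (elpd), estimated from the
#' retained pointwise log-likelihood draws with truncated
#' importance-sampling leave-one-out. Reports the standard error of
#' each model's elpd difference from the best model (paired over
#' trials).
#'
#' @param fits list of `agt_fit` objects on the same records (asserted
#'   by record count and checksum).
#' @return Object of class `agt_comparison`: data frame with name,
#'   elpd, se, elpd_diff (vs best), se_diff, rank, winner.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "agt_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "agt_fit")))
  sums <- vapply(fits, function(f) f$checksum, character(1))
  if (length(unique(sums)) != 1L)
    stop_invalid("all fits must be on the identical dataset (checksum mismatch)")
  loos <- lapply(fits, function(f) tis_loo(f$pointwise_ll))
  elpd <- vapply(loos, `[[`, numeric(1), "elpd")
  se <- vapply(loos, `[[`, numeric(1), "se")
  rk <- rank(-elpd, ties.method = "first")
  best <- which.min(rk)
  diff <- elpd - elpd[best]
  se_diff <- vapply(seq_along(loos), function(k) {
    d <- loos[[k]]$pointwise - loos[[best]]$pointwise
    sqrt(length(d) * stats::var(d))
  }, numeric(1))
  tab <- data.frame(
    name = vapply(fits, function(f) f$model$name, character(1)),
    elpd = elpd, se = se, elpd_diff = diff, se_diff = se_diff,
    rank = rk, winner = rk == 1L)
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  structure(list(table = tab), class = "agt_comparison")
}

#' @export
print.agt_comparison <- function(x, ...) {
  cat("model comparison (truncated-IS LOO):\n")
  t <- x$table
  t$elpd <- round(t$elpd, 2); t$se <- round(t$se, 2)
  t$elpd_diff <- round(t$elpd_diff, 2); t$se_diff <- round(t$se_diff, 2)
  print(t, row.names = FALSE)
  invisible(x)
}

#' Posterior-predictive check of acceptance rates
#'
#' Per-trial predicted acceptance probability averaged over the
#' retained posterior draws; compared with observed acceptance per
#' participant (Pearson r) and per reward x effort cell.
#'
#' @param fit an `agt_fit`.
#' @return List of class `agt_ppc`: `participant` (observed, predicted,
#'   per participant), `r` (NA with `r_defined = FALSE` if fewer than 3
#'   participants or zero variance), `cells` (4 x 4 observed and
#'   predicted matrices).
#' @export
posterior_predictive_acceptance <- function(fit) {
  stopifnot(inherits(fit, "agt_fit"))
  rec <- fit$records
  y <- as.logical(rec$accepted)
  # P(accept) per trial from the stored pointwise log-lik of the
  # observed choice: exp(ll) is p if accepted, 1-p if refused
  pobs <- exp(fit$pointwise_ll)
  p_acc <- colMeans(pobs)
  p_acc[!y] <- 1 - p_acc[!y]
  ids <- fit$participants$participant_id
  idx <- match(rec$participant_id, ids)
  obs <- as.numeric(tapply(y, idx, mean))
  pred <- as.numeric(tapply(p_acc, idx, mean))
  r_defined <- length(ids) >= 3 && stats::sd(obs) > 0 && stats::sd(pred) > 0
  r <- if (r_defined) stats::cor(obs, pred) else NA_real_
  rf <- factor(rec$reward_apples, levels = REWARD_LEVELS)
  ef <- factor(rec$effort_frac, levels = EFFORT_LEVELS)
  cells <- list(observed = tapply(as.numeric(y), list(rf, ef), mean),
                predicted = tapply(p_acc, list(rf, ef), mean))
  structure(list(participant = data.frame(participant_id = ids,
                                          observed = obs, predicted = pred),
                 r = r, r_defined = r_defined, cells = cells),
            class = "agt_ppc")
}

#' @export
print.agt_ppc <- function(x, ...) {
  if (x$r_defined)
    cat(sprintf("posterior-predictive acceptance: r = %.4f over %d participants\n",
                x$r, nrow(x$participant)))
  else
    cat("posterior-predictive acceptance: r undefined (too few participants or zero variance)\n")
  cat("predicted cell means (reward x effort):\n")
  print(round(x$cells$predicted, 3))
  invisible(x)
}

# default generative (mean, sd) per parameter for recovery studies
default_recovery_config <- function() {
  list(K = c(4, 3), LinR = c(13, 3), LinE = c(-15, 3), E2 = c(-2, 1.5),
       QuadR = c(10, 3), SqrtR = c(12, 3), LogR = c(14, 3),
       Hyp = c(0.7, 0.5), Expo = c(2, 0.6), Pow = c(1.5, 0.4))
}

#' Simulate choices from an arbitrary model specification
#'
#' @param spec an [agt_model_spec()].
#' @param theta matrix (participants x free parameters) of true values.
#' @param seed integer seed.
#' @param scaling an [agt_scaling()] object.
#' @param repetitions design repetitions per cell.
#' @return Long choice-record table with a `participant_id` column.
#' @export
simulate_from_model <- function(spec, theta, seed = 1L,
                                scaling = agt_scaling(), repetitions = 5L) {
  stopifnot(inherits(spec, "agt_model"), is.matrix(theta),
            ncol(theta) == length(spec$free_params))
  n <- nrow(theta)
  ids <- sprintf("P%03d", seq_len(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    d <- make_design(child_seed(seed, 2L * i), repetitions = repetitions)
    v <- model_value(spec, stats::setNames(theta[i, ], spec$free_params),
                     d$reward_apples, d$effort_frac, scaling)
    acc <- with_seed(child_seed(seed, 2L * i + 1L),
                     stats::runif(nrow(d)) < stats::plogis(v))
    out[[i]] <- data.frame(participant_id = ids[i], group = "all",
                           trial_index = d$trial_index,
                           reward_apples = d$reward_apples,
                           effort_frac = d$effort_frac,
                           accepted = acc)
  }
  do.call(rbind, out)
}

#' Parameter-recovery study
#'
#' Simulates a cohort from known parameters under `spec`, refits, and
#' correlates true with recovered (posterior-mean) values per free
#' parameter.
#'
#' @param spec an [agt_model_spec()].
#' @param n_participants cohort size.
#' @param seed integer seed.
#' @param method fitting backend ("map" or "mcmc").
#' @param config named list of c(mean, sd) generative settings per free
#'   parameter; defaults cover all registry parameters.
#' @param repetitions design repetitions per cell (80 trials at 5).
#' @param ... further arguments to [fit_agt()].
#' @return Object of class `agt_recovery`: per-parameter correlation
#'   (NA + flag when the true values have zero variance), mean signed
#'   error, config echo.
#' @export
run_recovery <- function(spec, n_participants = 100L, seed = 1L,
                         method = "map", config = default_recovery_config(),
                         repetitions = 5L, ...) {
  stopifnot(inherits(spec, "agt_model"))
  fp <- spec$free_params
  missing <- setdiff(fp, names(config))
  if (length(missing))
    stop_invalid("generator config missing parameter(s): %s",
                 paste(missing, collapse = ", "))
  theta <- with_seed(child_seed(seed, 541L), {
    m <- matrix(NA_real_, n_participants, length(fp),
                dimnames = list(NULL, fp))
    for (j in seq_along(fp))
      m[, j] <- stats::rnorm(n_participants, config[[fp[j]]][1],
                             config[[fp[j]]][2])
    m
  })
  recs <- simulate_from_model(spec, theta, seed = child_seed(seed, 542L),
                              repetitions = repetitions)
  fit <- fit_agt(recs, model = spec, method = method,
                 seed = child_seed(seed, 543L), ...)
  est <- fit$theta_mean
  rows <- lapply(seq_along(fp), function(j) {
    tv <- theta[, j]; ev <- est[, j]
    degenerate <- stats::sd(tv) == 0 || stats::sd(ev) == 0
    data.frame(parameter = fp[j],
               correlation = if (degenerate) NA_real_ else
                 stats::cor(tv, ev),
               mean_signed_error = mean(ev - tv),
               degenerate = degenerate)
  })
  structure(list(table = do.call(rbind, rows), truth = theta,
                 estimates = est, fit = fit,
                 config = list(n_participants = n_participants,
                               trials = 16L * repetitions, seed = seed,
                               method = method)),
            class = "agt_recovery")
}

#' @export
print.agt_recovery <- function(x, ...) {
  cat(sprintf("parameter recovery: %d participants x %d trials (%s, seed %d)\n",
              x$config$n_participants, x$config$trials,
              toupper(x$config$method), x$config$seed))
  t <- x$table
  t$correlation <- round(t$correlation, 3)
  t$mean_signed_error <- round(t$mean_signed_error, 3)
  print(t, row.names = FALSE)
  invisible(x)
}
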