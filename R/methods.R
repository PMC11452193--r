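# S3 methods for agt_fit objects.

#' @export
print.agt_fit <- function(x, ...) {
  cat(sprintf("hierarchical fit of '%s' (%s, scheme %s%s)\n", x$model$name,
              toupper(x$method), x$scheme,
              if (!is.null(x$param_of_interest))
                paste0(":", x$param_of_interest) else ""))
  cat(sprintf("  %d participants, %d trials, seed %d\n",
              nrow(x$participants), nrow(x$records), x$seed))
  cat("  group-level means:\n")
  h <- x$hyper
  for (k in seq_len(nrow(h)))
    cat(sprintf("    %-6s %-5s %8.3f (sd %.3f, group sd %.3f)\n",
                h$parameter[k], h$group[k], h$mean[k], h$mean_sd[k], h$sd[k]))
  if (length(x$model$constraints))
    cat("  constrained:",
        paste(names(x$model$constraints), x$model$constraints,
              sep = " = ", collapse = ", "), "\n")
  if (!is.na(x$diagnostics$max_rhat))
    cat(sprintf("  max R-hat %.3f\n", x$diagnostics$max_rhat))
  invisible(x)
}

#' Summarise a hierarchical fit
#'
#' @param object an `agt_fit`.
#' @param ... unused.
#' @return Object of class `summary.agt_fit` holding the per-participant
#'   parameter table (posterior mean/sd; constrained parameters appear
#'   with their fixed value and zero sd) and the group-level table.
#' @export
summary.agt_fit <- function(object, ...) {
  fp <- object$model$free_params
  ids <- object$participants$participant_id
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(fp))
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ids[i], parameter = fp[j],
        mean = object$theta_mean[i, j], sd = object$theta_sd[i, j],
        constrained = FALSE)
    for (cn in names(object$model$constraints))
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ids[i], parameter = cn,
        mean = unname(object$model$constraints[[cn]]), sd = 0,
        constrained = TRUE)
  }
  structure(list(participants = do.call(rbind, rows), hyper = object$hyper,
                 model = object$model, method = object$method),
            class = "summary.agt_fit")
}

#' @export
print.summary.agt_fit <- function(x, ...) {
  cat(sprintf("model '%s' (%s): %d participant-parameter estimates\n",
              x$model$name, toupper(x$method), nrow(x$participants)))
  cat("group-level table:\n")
  print(x$hyper, row.names = FALSE)
  cat("first participant rows:\n")
  print(utils::head(x$participants, 8), row.names = FALSE)
  invisible(x)
}

#' Participant-level posterior means
#'
#' @param object an `agt_fit`.
#' @param ... unused.
#' @return Matrix (participants x free parameters) of posterior means;
#'   constrained parameter values are attached as attribute
#'   `"constraints"`.
#' @export
coef.agt_fit <- function(object, ...) {
  out <- object$theta_mean
  attr(out, "constraints") <- object$model$constraints
  out
}

#' Predicted acceptance probabilities
#'
#' @param object an `agt_fit`.
#' @param newdata data frame with `reward_apples`, `effort_frac` and
#'   optionally `participant_id` (defaults to the fitted records).
#' @param ... unused.
#' @return Numeric vector of posterior-mean acceptance probabilities
#'   (probabilities under the posterior-mean parameters).
#' @export
predict.agt_fit <- function(object, newdata = NULL, ...) {
  nd <- newdata %||% object$records
  ids <- if ("participant_id" %in% names(nd)) nd$participant_id else
    rep(object$participants$participant_id[1], nrow(nd))
  idx <- match(ids, object$participants$participant_id)
  if (anyNA(idx)) stop_invalid("unknown participant_id in newdata")
  p <- numeric(nrow(nd))
  for (i in unique(idx)) {
    rows <- idx == i
    pars <- stats::setNames(object$theta_mean[i, ], object$model$free_params)
    v <- model_value(object$model, pars, nd$reward_apples[rows],
                     nd$effort_frac[rows], object$scaling)
    p[rows] <- stats::plogis(v)
  }
  p
}

#' Residuals of a fitted choice model
#'
#' @param object an `agt_fit`.
#' @param type `"response"` (observed - predicted probability) or
#'   `"pearson"`.
#' @param ... unused.
#' @return Numeric vector, one per trial in record order.
#' @export
residuals.agt_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  p <- predict(object)
  y <- as.numeric(object$records$accepted)
  r <- y - p
  if (type == "pearson") r <- r / sqrt(pmax(p * (1 - p), 1e-12))
  r
}

#' Simulate datasets from a fitted model
#'
#' Draws new accept/refuse choices for the fitted offers from the
#' posterior-mean acceptance probabilities.
#'
#' @param object an `agt_fit`.
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` data frames shaped like the fitted records.
#' @export
simulate.agt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  p <- predict(object)
  seed <- seed %||% object$seed
  out <- with_seed(seed, lapply(seq_len(nsim), function(s) {
    d <- object$records
    d$accepted <- stats::runif(length(p)) < p
    d
  }))
  out
}

#' Posterior-predictive acceptance plot
#'
#' Observed versus model-predicted per-participant acceptance rates,
#' plus the predicted acceptance curve over the reward x effort grid.
#'
#' @param x an `agt_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.agt_fit <- function(x, ...) {
  ppc <- posterior_predictive_acceptance(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(ppc$participant$observed, ppc$participant$predicted,
                 xlab = "observed acceptance", ylab = "predicted acceptance",
                 xlim = c(0, 1), ylim = c(0, 1),
                 main = sprintf("r = %.3f", ppc$r), ...)
  graphics::abline(0, 1, lty = 2)
  cellm <- ppc$cells$predicted
  graphics::matplot(EFFORT_LEVELS, t(cellm), type = "b", pch = 16,
                    xlab = "effort (fraction MVC)", ylab = "P(accept)",
                    ylim = c(0, 1), main = "predicted by reward level")
  graphics::legend("bottomleft", legend = paste(REWARD_LEVELS, "apples"),
                   col = seq_len(4), lty = seq_len(4), cex = 0.7)
  invisible(x)
}
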