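# Model space: factorial family of subjective-value choice models.
#
# Every model combines a reward term, an effort term and optionally an
# acceptance-bias intercept. Reward forms: linear, quadratic,
# linear+quadratic, square-root, log. Effort forms: none, linear,
# quadratic, linear+quadratic (additive costs) and hyperbolic,
# exponential, power (multiplicative discounts of the reward term).
# 5 x 7 x 2 = 70 candidate models; the winning model in both studies is
# linear reward + linear+quadratic effort + bias.

REWARD_FORMS <- c("linear", "quadratic", "linquad", "sqrt", "log")
EFFORT_FORMS <- c("none", "linear", "quadratic", "linquad",
                  "hyperbolic", "exponential", "power")

reward_param_names <- function(form) {
  switch(form,
         linear   = "LinR",
         quadratic = "QuadR",
         linquad  = c("LinR", "QuadR"),
         sqrt     = "SqrtR",
         log      = "LogR",
         stop_invalid("unknown reward form '%s'", form))
}

effort_param_names <- function(form) {
  switch(form,
         none     = character(0),
         linear   = "LinE",
         quadratic = "E2",
         linquad  = c("LinE", "E2"),
         hyperbolic = "Hyp",
         exponential = "Expo",
         power    = "Pow",
         stop_invalid("unknown effort form '%s'", form))
}

#' Construct a choice-model specification
#'
#' @param reward_form one of linear, quadratic, linquad, sqrt, log.
#' @param effort_form one of none, linear, quadratic, linquad (additive
#'   effort costs), hyperbolic, exponential, power (multiplicative
#'   discounts applied to the reward term).
#' @param include_bias include the acceptance-bias intercept K?
#' @param constraints named numeric vector fixing parameters (e.g.
#'   `c(LinE = -15)`); constrained parameters are excluded from fitting
#'   and from free-parameter counts.
#' @param name optional model name; derived from the forms by default.
#' @return An object of class `agt_model`.
#' @export
agt_model_spec <- function(reward_form, effort_form, include_bias = TRUE,
                           constraints = numeric(0), name = NULL) {
  reward_form <- match.arg(reward_form, REWARD_FORMS)
  effort_form <- match.arg(effort_form, EFFORT_FORMS)
  params <- c(if (include_bias) "K",
              reward_param_names(reward_form),
              effort_param_names(effort_form))
  if (length(constraints)) {
    if (is.null(names(constraints)) || any(!nzchar(names(constraints))))
      stop_invalid("constraints must be a named numeric vector")
    unknown <- setdiff(names(constraints), params)
    if (length(unknown))
      stop_invalid("constrained parameter(s) not in model: %s",
                   paste(unknown, collapse = ", "))
  }
  free <- setdiff(params, names(constraints))
  if (is.null(name)) {
    name <- sprintf("r-%s_e-%s_%s", reward_form, effort_form,
                    if (include_bias) "bias" else "nobias")
    if (length(constraints))
      name <- paste0(name, "_fix-",
                     paste(names(constraints), unname(constraints),
                           sep = "", collapse = "-"))
  }
  structure(list(name = name, reward_form = reward_form,
                 effort_form = effort_form, include_bias = include_bias,
                 constraints = constraints, params = params,
                 free_params = free),
            class = "agt_model")
}

#' @export
print.agt_model <- function(x, ...) {
  cat(sprintf("agt model '%s': reward %s, effort %s, bias %s\n", x$name,
              x$reward_form, x$effort_form,
              if (x$include_bias) "on" else "off"))
  cat(sprintf("  free parameters (%d): %s\n", length(x$free_params),
              paste(x$free_params, collapse = ", ")))
  if (length(x$constraints))
    cat(sprintf("  constrained: %s\n",
                paste(names(x$constraints), x$constraints,
                      sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Enumerate the factorial model registry
#'
#' All 70 combinations of 5 reward forms x 7 effort forms x bias on/off,
#' with deterministic unique names.
#'
#' @return A list of [agt_model_spec()] objects, length 70.
#' @examples
#' length(enumerate_models())  # 70
#' @export
enumerate_models <- function() {
  out <- list()
  for (r in REWARD_FORMS)
    for (e in EFFORT_FORMS)
      for (b in c(TRUE, FALSE))
        out[[length(out) + 1L]] <- agt_model_spec(r, e, include_bias = b)
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Export the model registry as a table
#'
#' @return data frame with one row per model: name, reward_form,
#'   effort_form, include_bias, constraints, n_free_parameters.
#' @export
model_registry_table <- function() {
  mods <- enumerate_models()
  data.frame(
    name = vapply(mods, `[[`, character(1), "name"),
    reward_form = vapply(mods, `[[`, character(1), "reward_form"),
    effort_form = vapply(mods, `[[`, character(1), "effort_form"),
    include_bias = vapply(mods, `[[`, logical(1), "include_bias"),
    constraints = vapply(mods, function(m)
      if (length(m$constraints))
        paste(names(m$constraints), m$constraints, sep = "=", collapse = ";")
      else "", character(1)),
    n_free_parameters = vapply(mods, function(m)
      length(m$free_params), integer(1)),
    row.names = NULL)
}

#' The winning model for each study
#'
#' Both studies selected linear reward + linear and quadratic effort
#' costs + acceptance bias. In the Pilot all four parameters (K, LinR,
#' LinE, E2) are free; in the Case-control study LinE is constrained to
#' the Pilot average, ConstE = -15, leaving three free parameters.
#'
#' @param study "pilot" or "case_control".
#' @return An `agt_model` specification.
#' @examples
#' winning_model("pilot")$free_params        # K LinR LinE E2
#' winning_model("case_control")$constraints # LinE = -15
#' @export
winning_model <- function(study = c("pilot", "case_control")) {
  study <- match.arg(study)
  if (study == "pilot")
    agt_model_spec("linear", "linquad", TRUE, name = "winning_pilot")
  else
    agt_model_spec("linear", "linquad", TRUE, constraints = c(LinE = -15),
                   name = "winning_case_control")
}

#' A bias-only null model
#'
#' Intercept-only comparison model: linear reward with LinR constrained
#' to 0 and no effort cost, so acceptance probability is constant.
#'
#' @return An `agt_model` specification with one free parameter, K.
#' @export
bias_only_model <- function() {
  agt_model_spec("linear", "none", TRUE, constraints = c(LinR = 0),
                 name = "bias_only")
}

# Full parameter vector from free values + constraints
full_param_vector <- function(spec, free_values) {
  if (is.null(names(free_values)))
    names(free_values) <- spec$free_params
  missing <- setdiff(spec$free_params, names(free_values))
  if (length(missing))
    stop_invalid("missing free parameter(s) for model '%s': %s",
                 spec$name, paste(missing, collapse = ", "))
  full <- c(free_values[spec$free_params], spec$constraints)
  full[spec$params]
}

# Subjective value under an arbitrary model spec; r, e already scaled.
# Multiplicative effort forms discount the reward term only; the bias
# (if any) is additive outside the discount.
model_value_scaled <- function(spec, full, r, e) {
  rterm <- switch(spec$reward_form,
                  linear   = full[["LinR"]] * r,
                  quadratic = full[["QuadR"]] * r^2,
                  linquad  = full[["LinR"]] * r + full[["QuadR"]] * r^2,
                  sqrt     = full[["SqrtR"]] * sqrt(r),
                  log      = full[["LogR"]] * log1p(r))
  v <- switch(spec$effort_form,
              none     = rterm,
              linear   = rterm + full[["LinE"]] * e,
              quadratic = rterm + full[["E2"]] * e^2,
              linquad  = rterm + full[["LinE"]] * e + full[["E2"]] * e^2,
              # Hyp is the log of the hyperbolic rate, so the discount
              # 1 / (1 + exp(Hyp) * e) is defined for every finite Hyp
              hyperbolic = rterm / (1 + exp(full[["Hyp"]]) * e),
              exponential = rterm * exp(-full[["Expo"]] * e),
              power    = rterm * e^full[["Pow"]])
  if (spec$include_bias) v <- v + full[["K"]]
  v
}

#' Subjective value under any model specification
#'
#' @param spec an [agt_model_spec()].
#' @param params named vector supplying every free parameter of `spec`;
#'   constrained parameters are taken from the spec.
#' @param reward_apples,effort_frac offer levels (vectorised).
#' @param scaling an [agt_scaling()] object.
#' @return Numeric vector of values (logits).
#' @export
model_value <- function(spec, params, reward_apples, effort_frac,
                        scaling = agt_scaling()) {
  stopifnot(inherits(spec, "agt_model"))
  check_offers(reward_apples, effort_frac)
  full <- full_param_vector(spec, params)
  model_value_scaled(spec, full,
                     scaling$reward_scale(reward_apples),
                     scaling$effort_scale(effort_frac))
}

#' Pointwise Bernoulli log-likelihood of choice records under a model
#'
#' Each accepted trial contributes log sigma(V), each refusal
#' log(1 - sigma(V)); exertion and success fields never enter the
#' likelihood.
#'
#' @param spec an [agt_model_spec()].
#' @param params named vector of free-parameter values.
#' @param records data frame with columns `reward_apples`, `effort_frac`,
#'   `accepted` (choice-record order is preserved).
#' @param scaling an [agt_scaling()] object.
#' @return Object of class `agt_loglik`: list with `pointwise` (numeric,
#'   one per trial, each <= 0) and `total`.
#' @examples
#' d <- make_design(1)
#' recs <- data.frame(reward_apples = d$reward_apples,
#'                    effort_frac = d$effort_frac, accepted = TRUE)
#' ll <- model_loglik(winning_model("pilot"),
#'                    c(K = 2, LinR = 4, LinE = -15, E2 = 0), recs)
#' ll$total
#' @export
model_loglik <- function(spec, params, records, scaling = agt_scaling()) {
  stopifnot(inherits(spec, "agt_model"))
  if (!all(c("reward_apples", "effort_frac", "accepted") %in% names(records)))
    stop_invalid("records must have reward_apples, effort_frac, accepted")
  v <- model_value(spec, params, records$reward_apples, records$effort_frac,
                   scaling)
  acc <- as.logical(records$accepted)
  # log sigma(v) for accepts, log sigma(-v) for refusals; saturates, no NaN
  pw <- ifelse(acc, stats::plogis(v, log.p = TRUE),
               stats::plogis(-v, log.p = TRUE))
  pw[!is.finite(v) & v == -Inf & acc] <- -Inf
  structure(list(pointwise = pw, total = sum(pw)), class = "agt_loglik")
}

#' @export
print.agt_loglik <- function(x, ...) {
  cat(sprintf("pointwise log-likelihood: %d trials, total %.4f\n",
              length(x$pointwise), x$total))
  invisible(x)
}
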