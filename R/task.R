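# Task core: AGT offer grid, predictor scaling, subjective value under the
# winning four-parameter model, logistic acceptance, arcsine transform.

REWARD_LEVELS <- c(3L, 6L, 9L, 12L)
EFFORT_LEVELS <- c(0.20, 0.40, 0.60, 0.80)

#' Predictor scaling for reward and effort
#'
#' Maps raw offer levels onto the unit interval before they enter the
#' subjective-value function. The default divides apples by the maximum
#' reward (12), giving scaled rewards 0.25..1, and leaves effort as the
#' fraction of maximum voluntary contraction (MVC), 0.2..0.8. With the
#' Case-control linear effort weight fixed at -15 this puts effort costs
#' at -3..-12 logits across the design, wide but not degenerate.
#'
#' @param reward_scale function mapping apple counts to scaled reward.
#' @param effort_scale function mapping effort fractions to scaled effort.
#' @return An object of class `agt_scaling`.
#' @examples
#' sc <- agt_scaling()
#' sc$reward_scale(c(3, 12))   # 0.25 1.00
#' @export
agt_scaling <- function(reward_scale = function(apples) apples / 12,
                        effort_scale = function(effort_frac) effort_frac) {
  stopifnot(is.function(reward_scale), is.function(effort_scale))
  r <- reward_scale(REWARD_LEVELS)
  e <- effort_scale(EFFORT_LEVELS)
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1) || any(diff(r) <= 0))
    stop_invalid("reward_scale must be strictly increasing into (0, 1] on levels %s",
                 paste(REWARD_LEVELS, collapse = ", "))
  if (any(!is.finite(e)) || any(e <= 0) || any(e > 1) || any(diff(e) <= 0))
    stop_invalid("effort_scale must be strictly increasing into (0, 1] on levels %s",
                 paste(EFFORT_LEVELS, collapse = ", "))
  structure(list(reward_scale = reward_scale, effort_scale = effort_scale),
            class = "agt_scaling")
}

#' Generate a session design
#'
#' Builds the full factorial offer grid -- 4 reward levels (3, 6, 9, 12
#' apples) by 4 effort levels (20, 40, 60, 80% MVC) -- repeats each cell
#' `repetitions` times (default 5, i.e. 80 trials) and permutes trial
#' order deterministically under `seed`.
#'
#' @param seed integer seed controlling the trial-order permutation.
#' @param repetitions repetitions of each reward x effort cell (>= 1).
#' @return A data frame of class `agt_design` with columns `trial_index`,
#'   `reward_apples`, `effort_frac`, `repetition_index`.
#' @examples
#' d <- make_design(seed = 1)
#' nrow(d)                       # 80
#' table(d$reward_apples, d$effort_frac)  # every cell 5
#' @export
make_design <- function(seed, repetitions = 5L) {
  if (!is.numeric(repetitions) || length(repetitions) != 1L ||
      !is.finite(repetitions) || repetitions < 1 || repetitions != floor(repetitions))
    stop_invalid("repetitions must be a positive integer (got %s)",
                 format(repetitions))
  repetitions <- as.integer(repetitions)
  grid <- expand.grid(reward_apples = REWARD_LEVELS,
                      effort_frac   = EFFORT_LEVELS,
                      repetition_index = seq_len(repetitions),
                      KEEP.OUT.ATTRS = FALSE)
  ord <- with_seed(seed, sample.int(nrow(grid)))
  out <- grid[ord, , drop = FALSE]
  out <- data.frame(trial_index = seq_len(nrow(out)),
                    reward_apples = out$reward_apples,
                    effort_frac = out$effort_frac,
                    repetition_index = out$repetition_index)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("agt_design", "data.frame")
  out
}

#' Parameter set for the winning subjective-value model
#'
#' @param K acceptance bias (logit intercept; higher = more likely to accept).
#' @param LinR linear reward sensitivity (positive = rewards valued more).
#' @param LinE linear effort sensitivity (more negative = effort costlier).
#' @param E2 quadratic effort sensitivity (negative = disproportionate cost
#'   at high effort).
#' @return A named numeric vector of class `agt_params`.
#' @export
agt_params <- function(K = 0, LinR = 0, LinE = 0, E2 = 0) {
  p <- c(K = K, LinR = LinR, LinE = LinE, E2 = E2)
  if (any(!is.finite(p))) stop_invalid("all parameters must be finite")
  structure(p, class = "agt_params")
}

#' Subjective value of an offer
#'
#' Computes V = K + LinR * r + LinE * e + E2 * e^2 where r and e are the
#' scaled reward and effort of the offer. Vectorised over offers.
#'
#' @param params an [agt_params()] vector or any named vector with entries
#'   K, LinR, LinE, E2.
#' @param reward_apples apple counts.
#' @param effort_frac effort levels as fractions of MVC.
#' @param scaling an [agt_scaling()] object.
#' @return Numeric vector of subjective values (logits).
#' @examples
#' subjective_value(agt_params(K = 2, LinR = 4, LinE = -15), 12, 0.20)  # 3
#' @export
subjective_value <- function(params, reward_apples, effort_frac,
                             scaling = agt_scaling()) {
  params <- as_params(params)
  check_offers(reward_apples, effort_frac)
  r <- scaling$reward_scale(reward_apples)
  e <- scaling$effort_scale(effort_frac)
  params[["K"]] + params[["LinR"]] * r + params[["LinE"]] * e +
    params[["E2"]] * e^2
}

#' Probability of accepting an offer
#'
#' Logistic choice rule sigma(V) = 1 / (1 + exp(-V)) applied to the
#' subjective value; saturates at 0/1 without overflow.
#'
#' @inheritParams subjective_value
#' @return Acceptance probabilities in (0, 1) (exactly 0/1 only at
#'   infinite value).
#' @export
accept_probability <- function(params, reward_apples, effort_frac,
                               scaling = agt_scaling()) {
  stats::plogis(subjective_value(params, reward_apples, effort_frac, scaling))
}

#' Arcsine-square-root transform of a proportion
#'
#' asin(sqrt(p)), the classical variance-stabilising transform applied to
#' acceptance rates before Gaussian-assumption analyses. Maps 0 to 0 and
#' 1 to pi/2 exactly.
#'
#' @param p proportions in \[0, 1\]; NA passes through.
#' @return Transformed values in \[0, pi/2\].
#' @export
arcsine_transform <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1 | !is.finite(p))
  if (any(bad))
    stop_invalid("proportions must lie in [0, 1]; offending values: %s",
                 paste(utils::head(p[bad], 5), collapse = ", "))
  asin(sqrt(p))
}

# --- internal validation -------------------------------------------------

as_params <- function(params) {
  if (inherits(params, "agt_params")) return(params)
  if (is.numeric(params) && !is.null(names(params))) {
    full <- c(K = 0, LinR = 0, LinE = 0, E2 = 0)
    unknown <- setdiff(names(params), names(full))
    if (length(unknown))
      stop_invalid("unknown parameter(s): %s", paste(unknown, collapse = ", "))
    full[names(params)] <- params
    if (any(!is.finite(full))) stop_invalid("all parameters must be finite")
    return(structure(full, class = "agt_params"))
  }
  stop_invalid("params must be an agt_params object or named numeric vector")
}

check_offers <- function(reward_apples, effort_frac) {
  if (!all(reward_apples %in% REWARD_LEVELS))
    stop_invalid("reward_apples must be one of %s",
                 paste(REWARD_LEVELS, collapse = ", "))
  ok <- vapply(effort_frac,
               function(e) any(abs(e - EFFORT_LEVELS) < 1e-9), logical(1))
  if (!all(ok))
    stop_invalid("effort_frac must be one of %s",
                 paste(EFFORT_LEVELS, collapse = ", "))
  invisible(TRUE)
}

# index 1..4 of each effort level
effort_level_index <- function(effort_frac) {
  idx <- vapply(effort_frac,
                function(e) which.min(abs(e - EFFORT_LEVELS)), integer(1))
  idx
}
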