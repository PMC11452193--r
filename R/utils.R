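# Internal helpers: seeded evaluation, seed streams, hashing.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so package functions are deterministic without
#' clobbering the caller's random stream.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else if
      (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from (seed, index); keeps results < 2^31 and decorrelates
# streams used by different stages/participants.
child_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807 + 12345) %% 2147483629
  as.integer(s) + 1L
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# md5 checksum of a character vector (used to assert dataset identity)
hash_strings <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(x, f)
  unname(tools::md5sum(f))
}

# checksum of a choice-record table: participant, trial, offer, outcome
records_checksum <- function(records) {
  hash_strings(paste(records$participant_id, records$trial_index,
                     records$reward_apples, records$effort_frac,
                     as.integer(records$accepted), sep = ","))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
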