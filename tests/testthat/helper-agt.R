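# shared fixtures, built in code

# quick single-participant record table over a full design
toy_records <- function(params = c(K = 2, LinR = 4, LinE = -15, E2 = 0),
                        seed = 1, id = "P1", accepted = NULL) {
  d <- make_design(seed)
  acc <- if (!is.null(accepted)) rep(accepted, length.out = nrow(d)) else
    with_seed_local(seed, stats::runif(nrow(d)) <
                      accept_probability(params, d$reward_apples,
                                         d$effort_frac))
  data.frame(participant_id = id, group = "all",
             trial_index = d$trial_index,
             reward_apples = d$reward_apples, effort_frac = d$effort_frac,
             accepted = acc)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# small multi-participant dataset from the winning case-control model
small_cc_dataset <- function(n = 12, seed = 3) {
  spec <- winning_model("case_control")
  theta <- with_seed_local(seed, cbind(K = rnorm(n, 4, 3),
                                       LinR = rnorm(n, 13, 3),
                                       E2 = rnorm(n, -2, 1.5)))
  list(records = simulate_from_model(spec, theta, seed = seed + 1),
       theta = theta, spec = spec)
}
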