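# Hierarchical fitting: validation, pooling, constraints, schemes.

test_that("fit validation rejects degenerate inputs", {
  recs <- toy_records()
  expect_error(fit_agt(recs[0, ]), "empty")
  expect_error(fit_agt(recs), ">= 2 participants")  # single participant
  two <- rbind(toy_records(id = "P1"), toy_records(id = "P2", seed = 2))
  allfix <- agt_model_spec("linear", "none",
                           constraints = c(K = 0, LinR = 0))
  expect_error(fit_agt(two, model = allfix), "no free parameters")
  no_grp <- two[, setdiff(names(two), "group")]
  expect_error(fit_agt(no_grp, scheme = "per_group",
                       param_of_interest = "K"), "group column")
  expect_error(fit_agt(two, scheme = "per_group",
                       param_of_interest = "Zzz"), "param_of_interest")
})

test_that("all-accept data forces a positive acceptance-bias hypermean", {
  recs <- do.call(rbind, lapply(1:4, function(i)
    toy_records(id = paste0("P", i), seed = i, accepted = TRUE)))
  f <- fit_agt(recs, model = bias_only_model(), method = "map", seed = 1)
  expect_gt(f$hyper$mean[f$hyper$parameter == "K"], 0)
  expect_true(all(f$theta_mean[, "K"] > 0))
})

test_that("constrained LinE is reported as exactly -15 with zero sd", {
  dat <- small_cc_dataset(n = 6)
  f <- fit_agt(dat$records, model = winning_model("case_control"),
               method = "map", seed = 2)
  sm <- summary(f)
  le <- sm$participants[sm$participants$parameter == "LinE", ]
  expect_equal(nrow(le), 6L)
  expect_true(all(le$mean == -15))
  expect_true(all(le$sd == 0))
  expect_true(all(le$constrained))
  expect_false("LinE" %in% colnames(coef(f)))
})

test_that("MAP recovers hypermeans on data simulated at the stated scale", {
  # 40 participants x 80 trials from the pilot winning model with
  # generative K hypermean 1.5: posterior mean of the K hypermean
  # within 0.5 of truth
  spec <- winning_model("pilot")
  theta <- with_seed_local(31, cbind(K = rnorm(40, 1.5, 1.5),
                                     LinR = rnorm(40, 13, 3),
                                     LinE = rnorm(40, -15, 3),
                                     E2 = rnorm(40, -2, 1.5)))
  recs <- simulate_from_model(spec, theta, seed = 32)
  f <- fit_agt(recs, model = spec, method = "map", seed = 33)
  k_hat <- f$hyper$mean[f$hyper$parameter == "K"]
  expect_lt(abs(k_hat - 1.5), 0.5)
})

test_that("posterior means shrink toward the hypermean", {
  # scalar model: partial pooling places each posterior mean between
  # the participant's no-pooling MLE (logit of their acceptance rate,
  # +/- Inf under saturation) and the group hypermean
  spec <- bias_only_model()
  theta <- with_seed_local(9, matrix(rnorm(60, 0.5, 1.2), ncol = 1,
                                     dimnames = list(NULL, "K")))
  recs <- simulate_from_model(spec, theta, seed = 10)
  f <- fit_agt(recs, model = spec, method = "map", seed = 11)
  mu <- f$hyper$mean
  ids <- f$participants$participant_id
  between <- vapply(seq_along(ids), function(i) {
    acc <- mean(recs$accepted[recs$participant_id == ids[i]])
    mle <- if (acc %in% c(0, 1)) sign(acc - 0.5) * Inf else
      stats::qlogis(acc)
    pk <- f$theta_mean[i, 1]
    pk >= min(mle, mu) - 1e-9 && pk <= max(mle, mu) + 1e-9
  }, logical(1))
  expect_gte(mean(between), 0.9)

  # multi-parameter model: componentwise betweenness is not a theorem
  # for correlated posteriors, but the posterior vector contracts
  # toward the hypermean relative to the unpooled MLE
  dat <- small_cc_dataset(n = 20, seed = 13)
  fm <- fit_agt(dat$records, model = dat$spec, method = "map", seed = 14)
  mu3 <- stats::setNames(fm$hyper$mean, fm$hyper$parameter)
  ids3 <- fm$participants$participant_id
  contracts <- vapply(seq_along(ids3), function(i) {
    r <- dat$records[dat$records$participant_id == ids3[i], ]
    X <- cbind(1, r$reward_apples / 12, r$effort_frac^2)
    g <- suppressWarnings(stats::glm.fit(
      X, as.numeric(r$accepted), offset = -15 * r$effort_frac,
      family = stats::binomial()))
    mle <- g$coefficients
    post <- fm$theta_mean[i, ]
    sqrt(sum((post - mu3[colnames(fm$theta_mean)])^2)) <=
      sqrt(sum((mle - mu3[colnames(fm$theta_mean)])^2)) + 1e-6
  }, logical(1))
  expect_gte(mean(contracts), 0.9)
})

test_that("prior schemes: single-group equivalence and sensitivity", {
  dat <- small_cc_dataset(n = 10, seed = 23)
  f_sh <- fit_agt(dat$records, model = dat$spec, scheme = "shared",
                  method = "map", seed = 5)
  f_pg <- fit_agt(dat$records, model = dat$spec, scheme = "per_group",
                  param_of_interest = "K", method = "map", seed = 5)
  # one group: per-group priors degenerate to the shared scheme
  h1 <- f_sh$hyper$mean[f_sh$hyper$parameter == "K"]
  h2 <- f_pg$hyper$mean[f_pg$hyper$parameter == "K"]
  se <- f_sh$hyper$mean_sd[f_sh$hyper$parameter == "K"]
  expect_lt(abs(h1 - h2), 2 * se)

  # two groups with a planted K shift: separate priors for all
  # parameters change the K group-mean difference by < 0.2 posterior sd
  coh <- simulate_cohort(list(group_spec("CTR", 12),
                              group_spec("MDD", 12, K_mean = 2.8)),
                         seed = 44)
  fa <- fit_agt(coh$records, model = winning_model("case_control"),
                scheme = "per_group", param_of_interest = "K",
                method = "map", seed = 6)
  fb <- fit_agt(coh$records, model = winning_model("case_control"),
                scheme = "per_group_all", method = "map", seed = 6)
  dk <- function(f) {
    h <- f$hyper[f$hyper$parameter == "K", ]
    h$mean[h$group == "CTR"] - h$mean[h$group == "MDD"]
  }
  sd_ref <- mean(fa$hyper$mean_sd[fa$hyper$parameter == "K"])
  expect_lt(abs(dk(fa) - dk(fb)), 0.2 * sd_ref * 2 + 0.2)
  # both schemes find the planted direction
  expect_gt(dk(fa), 0)
  expect_gt(dk(fb), 0)
})

test_that("MCMC backend samples, diagnoses and matches MAP estimates", {
  dat <- small_cc_dataset(n = 8, seed = 51)
  f_mc <- suppressWarnings(
    fit_agt(dat$records, model = dat$spec, method = "mcmc",
            chains = 2, iter = 300, warmup = 300, seed = 9))
  expect_equal(dim(f_mc$draws), c(600L, 8L, 3L))
  expect_false(is.null(f_mc$diagnostics$rhat))
  expect_true(all(is.finite(f_mc$diagnostics$rhat$rhat)))
  # MAP and MCMC point estimates agree within tolerance on these data
  f_map <- fit_agt(dat$records, model = dat$spec, method = "map", seed = 9)
  expect_gt(cor(c(f_map$theta_mean), c(f_mc$theta_mean)), 0.95)
  # determinism contract
  f_mc2 <- suppressWarnings(
    fit_agt(dat$records, model = dat$spec, method = "mcmc",
            chains = 2, iter = 300, warmup = 300, seed = 9))
  expect_identical(f_mc$theta_mean, f_mc2$theta_mean)
})

test_that("fit methods: coef, predict, residuals, simulate, summary", {
  dat <- small_cc_dataset(n = 6, seed = 61)
  f <- fit_agt(dat$records, model = dat$spec, method = "map", seed = 3)
  cf <- coef(f)
  expect_equal(dim(cf), c(6L, 3L))
  expect_equal(attr(cf, "constraints"), c(LinE = -15))
  p <- predict(f)
  expect_length(p, nrow(dat$records))
  expect_true(all(p > 0 & p < 1))
  r <- residuals(f)
  expect_equal(r, as.numeric(dat$records$accepted) - p)
  sims <- simulate(f, nsim = 2, seed = 10)
  expect_length(sims, 2L)
  expect_equal(nrow(sims[[1]]), nrow(dat$records))
  expect_output(print(f), "hierarchical fit")
  expect_output(print(summary(f)), "group-level")
})
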