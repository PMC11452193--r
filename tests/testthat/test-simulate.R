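# Synthetic cohort: calibration, sessions, cohorts, symptom factors.

test_that("MVC calibration returns the peak of the final three squeezes", {
  res <- simulate_calibration(300, noise_sd = 0, seed = 1)
  expect_equal(res$mvc, 300)
  for (s in c(1, 5, 9)) {
    r <- simulate_calibration(250, noise_sd = 30, seed = s)
    expect_true(all(r$mvc >= r$squeezes[4:6]))
    expect_true(r$mvc %in% r$squeezes[4:6])
    expect_true(all(r$squeezes > 0))
  }
  # Monte-Carlo oracle: the max of three noisy draws exceeds the mean
  mvcs <- vapply(1:2000, function(s)
    simulate_calibration(100, noise_sd = 15, seed = s)$mvc, numeric(1))
  expect_gt(mean(mvcs), 100)
  expect_error(simulate_calibration(-5, 1, 1), "positive")
})

test_that("session simulation applies the exact 25% omission rule", {
  d <- make_design(2)
  # saturated acceptance: all 80 accepted, exactly 20 exertion-omitted
  s <- simulate_session(c(K = 50), d, seed = 7)
  expect_true(all(s$accepted))
  expect_equal(sum(!s$exertion_required), 20L)
  # saturated refusal: nothing accepted, no exertion, no successes
  s0 <- simulate_session(c(K = -50), d, seed = 7)
  expect_false(any(s0$accepted))
  expect_false(any(s0$exertion_required))
  expect_true(all(is.na(s0$success)))
  # degenerate success model: every exerted trial succeeds
  s1 <- simulate_session(c(K = 50), d, seed = 3,
                         success = success_model(c(1, 1, 1, 1) - 1e-9))
  expect_true(all(s1$success[s1$exertion_required]))
  # rounding half away from zero at small counts: 2 accepted -> 1 omitted
  expect_equal(agtfit:::round_half_away(0.25 * 2), 1)
  expect_equal(agtfit:::round_half_away(0.25 * 6), 2)
})

test_that("refused trials never carry exertion or success", {
  coh <- simulate_cohort(list(group_spec("HV", 8)), seed = 5)
  ref <- coh$records[!coh$records$accepted, ]
  expect_false(any(ref$exertion_required))
  expect_true(all(is.na(ref$success)))
  # success only defined where exerted
  expect_true(all(!is.na(coh$records$success[coh$records$exertion_required])))
  expect_true(all(is.na(coh$records$success[!coh$records$exertion_required])))
})

test_that("cohort assembly is sized, grouped and reproducible", {
  specs <- list(group_spec("CTR", 3), group_spec("MDD", 2))
  coh <- simulate_cohort(specs, seed = 9)
  expect_equal(nrow(coh$truth), 5L)
  expect_equal(nrow(coh$records), 5L * 80L)
  expect_equal(sort(unique(coh$truth$group)), c("CTR", "MDD"))
  expect_true(all(coh$truth$mvc > 0))
  expect_true(all(coh$truth$age >= 18 & coh$truth$age <= 60))
  # determinism
  coh2 <- simulate_cohort(specs, seed = 9)
  expect_identical(coh$records, coh2$records)
  expect_identical(coh$truth, coh2$truth)
  # zero group sd: identical true parameters within the group
  cz <- simulate_cohort(list(group_spec("HV", 4, K_sd = 0, LinR_sd = 0,
                                        LinE_sd = 0, E2_sd = 0)), seed = 2)
  expect_equal(length(unique(cz$truth$K)), 1L)
  expect_equal(length(unique(cz$truth$E2)), 1L)
  expect_error(simulate_cohort(list()), "non-empty")
})

test_that("default cohort reproduces the study's acceptance structure", {
  specs <- default_cohort("case_control")
  expect_equal(vapply(specs, `[[`, integer(1), "n"), c(57L, 36L, 46L, 41L))
  coh <- simulate_cohort(specs, seed = 1)
  expect_equal(nrow(coh$records), 180L * 80L)
  a <- coh$truth$acceptance_rate
  # wide spread of overall acceptance (study range 40-100%)
  expect_lt(min(a), 0.55)
  expect_gt(max(a), 0.95)
  # acceptance decreases with effort and increases with reward,
  # Wilcoxon sign over participants on adjacent levels
  cmat <- t(vapply(split(coh$records, coh$records$participant_id),
                   function(r) as.vector(acceptance_matrix(r)$matrix),
                   numeric(16)))  # 4x4 flattened, reward fastest
  eff_means <- sapply(0:3, function(e) rowMeans(cmat[, e * 4 + 1:4]))
  rew_means <- sapply(1:4, function(r) rowMeans(cmat[, r + c(0, 4, 8, 12)]))
  for (j in 1:3) {
    expect_lt(stats::wilcox.test(eff_means[, j + 1], eff_means[, j],
                                 paired = TRUE,
                                 alternative = "less")$p.value, 1e-6)
    expect_lt(stats::wilcox.test(rew_means[, j + 1], rew_means[, j],
                                 paired = TRUE,
                                 alternative = "greater")$p.value, 1e-6)
  }
})

test_that("symptom factors hit their target correlations", {
  n <- 10000
  truth <- data.frame(participant_id = seq_len(n),
                      K = rnorm(n), LinR = rnorm(n), E2 = rnorm(n))
  # independence at rho = 0
  f0 <- simulate_symptom_factors(
    truth, data.frame(factor = "F0", parameter = "K", rho = 0), seed = 1)
  expect_lt(abs(cor(f0$F0, truth$K)), 0.1)
  # the Pilot Low Mood-LinR association at rho = -0.344
  fl <- simulate_symptom_factors(
    truth, data.frame(factor = "LowMood", parameter = "LinR",
                      rho = -0.344), seed = 2)
  expect_lt(abs(cor(fl$LowMood, truth$LinR) - (-0.344)), 0.03)
  # perfect correlation is an affine transform
  f1 <- simulate_symptom_factors(
    truth, data.frame(factor = "F1", parameter = "E2", rho = 1), seed = 3)
  expect_equal(cor(f1$F1, truth$E2), 1, tolerance = 1e-12)
  expect_error(simulate_symptom_factors(
    truth, data.frame(factor = "F", parameter = "K", rho = 1.2)),
    "\\[-1, 1\\]")
  # default loadings cover the four named factors
  def <- simulate_symptom_factors(truth, seed = 4)
  expect_setequal(setdiff(names(def), "participant_id"),
                  c("LowMood", "Apathy", "Hedonia",
                    "DysfunctionalAttitudes"))
})

test_that("success probabilities respect the >80% top-effort bound", {
  expect_error(success_model(c(0.97, 0.95, 0.92, 0.75)), "0.80")
  sm <- success_model()
  expect_true(all(unclass(sm) > 0.80))
  # empirical success at the top effort level stays above 80%
  coh <- simulate_cohort(list(group_spec("HV", 30)), seed = 8)
  top <- coh$records[coh$records$effort_frac == 0.8 &
                       coh$records$exertion_required, ]
  expect_gt(mean(top$success), 0.80)
})
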