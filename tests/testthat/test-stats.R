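# Model-agnostic statistics: acceptance tables, RM-ANOVA, contrasts,
# power, correlations.

test_that("acceptance matrix counts cells correctly", {
  d <- make_design(1)
  all_acc <- data.frame(d, accepted = TRUE)
  am <- acceptance_matrix(all_acc)
  expect_true(all(am$matrix == 1))
  expect_equal(am$overall, 1)
  expect_true(all(am$counts == 5))

  none <- data.frame(d, accepted = FALSE)
  expect_true(all(acceptance_matrix(none)$matrix == 0))

  # exactly the 3-apple / 80% cell always refused
  sel <- d$reward_apples == 3 & d$effort_frac == 0.8
  mix <- data.frame(d, accepted = !sel)
  am2 <- acceptance_matrix(mix)
  expect_equal(am2$matrix["3", "0.8"], 0)
  expect_true(all(am2$matrix[am2$matrix != 0] == 1))
  expect_equal(am2$overall, 75 / 80)

  # missing cells are flagged, not silently zero
  part <- all_acc[d$reward_apples != 12, ]
  amp <- acceptance_matrix(part)
  expect_length(amp$missing_cells, 4L)
  expect_true(all(is.na(amp$matrix["12", ])))
})

test_that("rm_anova matches an explicit design-matrix GLM oracle", {
  # 6 participants, 2-level within factor, 2 groups: compute the
  # split-plot F values from scratch with projection algebra
  set.seed(10)
  Y <- matrix(rnorm(12, mean = rep(c(0, 0.8), each = 6)), 6, 2)
  grp <- rep(c("a", "b"), each = 3)
  mine <- rm_anova_matrix(Y, within = c(cond = 2L), group = grp)$table

  # oracle: long-format GLM with explicit design matrices
  y <- c(Y)
  subj <- factor(rep(1:6, 2)); w <- factor(rep(1:2, each = 6))
  g <- factor(rep(grp, 2))
  ss <- function(X, yy) {       # residual SS after projecting on X
    Q <- qr.Q(qr(X)); sum((yy - Q %*% crossprod(Q, yy))^2)
  }
  # between stratum: subject means
  sm <- as.numeric(tapply(y, subj, mean)); gs <- factor(grp)
  ss_group <- ss(matrix(1, 6, 1), sm) - ss(stats::model.matrix(~gs), sm)
  ss_subj <- ss(stats::model.matrix(~gs), sm)
  F_group <- (ss_group / 1) / (ss_subj / 4)
  # within stratum: orthonormal difference scores (y1 - y2) / sqrt(2)
  d2 <- as.numeric(tapply(y, subj, function(v) v[1] - v[2])) / sqrt(2)
  gm <- tapply(d2, gs, mean); ng <- table(gs)
  sse_w <- sum((d2 - gm[gs])^2)
  F_cond <- (sum(ng) * mean(d2)^2) / (sse_w / 4)
  F_wg <- sum(ng * (gm - mean(d2))^2) / (sse_w / 4)

  expect_equal(mine$F[mine$effect == "group"], F_group, tolerance = 1e-8)
  expect_equal(mine$F[mine$effect == "cond"], F_cond, tolerance = 1e-8)
  expect_equal(mine$F[mine$effect == "cond:group"], F_wg, tolerance = 1e-8)
  # epsilon is identically 1 for any 2-level factor
  expect_equal(mine$epsilon[mine$effect == "cond"], 1)
})

test_that("rm_anova agrees with aov on a 4-level within design", {
  set.seed(11)
  Y <- matrix(rnorm(32, mean = rep(c(0, .5, 1, 1.5), each = 8)), 8, 4)
  mine <- rm_anova_matrix(Y, within = c(w = 4L))$table
  long <- data.frame(y = c(Y), w = factor(rep(1:4, each = 8)),
                     s = factor(rep(1:8, 4)))
  av <- summary(stats::aov(y ~ w + Error(s / w), long))
  Fa <- av[["Error: s:w"]][[1]]["w", "F value"]
  expect_equal(mine$F[mine$effect == "w"], Fa, tolerance = 1e-10)
})

test_that("epsilon approaches 1 under population sphericity", {
  # compound-symmetric data: independent subject intercepts + iid noise
  eps <- replicate(10, {
    n <- 200
    Y <- matrix(rnorm(n * 4), n, 4) + rnorm(n, sd = 1)
    rm_anova_matrix(Y, within = c(w = 4L))$table$epsilon[1]
  })
  expect_gt(mean(eps), 0.9)
})

test_that("full AGT anova runs and the transform matters near bounds", {
  coh <- simulate_cohort(list(group_spec("CTR", 8), group_spec("MDD", 8)),
                         seed = 21)
  a1 <- rm_anova(coh$records, transform = "arcsine")
  a2 <- rm_anova(coh$records, transform = "none")
  expect_s3_class(a1, "agt_anova")
  effs <- a1$table$effect
  expect_true(all(c("reward", "effort", "reward:effort", "group", "age")
                  %in% effs))
  # arcsine applied before (and only before) the ANOVA: bounded data
  # yields different F values on the two scales
  expect_false(isTRUE(all.equal(
    a1$table$F[a1$table$effect == "effort"],
    a2$table$F[a2$table$effect == "effort"])))
  # corrected df equals uncorrected df times epsilon
  wrow <- a1$table[a1$table$effect == "effort", ]
  expect_equal(wrow$df1_gg, wrow$df1 * wrow$epsilon)
  expect_true(wrow$epsilon > 0 && wrow$epsilon <= 1)
})

test_that("planned contrasts: d conventions and covariate handling", {
  # identical distributions
  v <- rep(c(1, 2, 3), 4)
  g <- rep(c("A", "B"), each = 6)
  expect_equal(planned_contrast(v, g, "A", "B")$d, 0)
  # definitional d: means 1 and 0, common sd 1
  set.seed(3)
  x1 <- rnorm(200); x1 <- (x1 - mean(x1)) / sd(x1) + 1
  x2 <- rnorm(200); x2 <- (x2 - mean(x2)) / sd(x2)
  ct <- planned_contrast(c(x1, x2), rep(c("A", "B"), each = 200), "A", "B")
  expect_equal(ct$d, 1, tolerance = 1e-10)
  # shift invariance and sign flip
  ct_shift <- planned_contrast(c(x1, x2) + 100,
                               rep(c("A", "B"), each = 200), "A", "B")
  expect_equal(ct_shift$d, ct$d, tolerance = 1e-10)
  ct_rev <- planned_contrast(c(x1, x2), rep(c("A", "B"), each = 200),
                             "B", "A")
  expect_equal(ct_rev$d, -ct$d, tolerance = 1e-10)
  # covariate changes F but never d
  cv <- rnorm(400)
  ct_cov <- planned_contrast(c(x1, x2), rep(c("A", "B"), each = 200),
                             "A", "B", covariate = cv)
  expect_equal(ct_cov$d, ct$d, tolerance = 1e-10)
  expect_error(planned_contrast(c(1, 2, 3), c("A", "A", "B"), "A", "B"),
               ">= 2")
})

test_that("noncentral-F power behaves at the boundaries and is monotone", {
  n4 <- c(57, 36, 46, 41)
  expect_equal(anova_power(0, n4), 0.05, tolerance = 1e-10)
  expect_gt(anova_power(10, n4), 0.999)
  # monotone in f, N, alpha
  fs <- seq(0.05, 0.6, by = 0.05)
  expect_true(all(diff(vapply(fs, anova_power, numeric(1), n = n4)) > 0))
  expect_gt(anova_power(0.25, n4 * 2), anova_power(0.25, n4))
  expect_gt(anova_power(0.25, n4, alpha = 0.1),
            anova_power(0.25, n4, alpha = 0.01))
  expect_error(anova_power(-1, n4), ">= 0")
  expect_error(anova_power(0.2, n4, alpha = 1.2), "alpha")
})

test_that("parameter-symptom correlation handles edge cases", {
  x <- rnorm(50)
  r1 <- correlate_params_symptoms(x, x)
  expect_equal(r1$r, 1)
  expect_lt(r1$p, 1e-10)
  set.seed(5)
  r0 <- correlate_params_symptoms(rnorm(10000), rnorm(10000))
  expect_lt(abs(r0$r), 0.05)
  # zero variance flagged, listwise deletion reported
  rz <- correlate_params_symptoms(rep(1, 10), rnorm(10))
  expect_true(rz$degenerate)
  expect_true(is.na(rz$r))
  rm <- correlate_params_symptoms(c(x, NA), c(rnorm(50), 1))
  expect_equal(rm$n_dropped, 1L)
  expect_error(correlate_params_symptoms(1:2, 2:3), ">= 3")
})

test_that("a planted symptom correlation is recovered at the Pilot n", {
  # target r = -0.344 at n = 67: sample r falls inside the 95% sampling
  # interval of the target in >= 18 of 20 seeded replicates
  z <- atanh(-0.344); se <- 1 / sqrt(67 - 3)
  lo <- tanh(z - 1.96 * se); hi <- tanh(z + 1.96 * se)
  hits <- 0L
  for (s in 1:20) {
    truth <- data.frame(participant_id = 1:67, LinR = rnorm(67, 13, 3))
    f <- simulate_symptom_factors(
      truth, data.frame(factor = "LowMood", parameter = "LinR",
                        rho = -0.344), seed = s)
    r <- correlate_params_symptoms(truth$LinR, f$LowMood)$r
    hits <- hits + (r >= lo && r <= hi)
  }
  expect_gte(hits, 18L)
})
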