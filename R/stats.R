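# Model-agnostic statistical arm: acceptance matrices, mixed
# repeated-measures ANOVA with Greenhouse-Geisser correction, planned
# contrasts with Cohen's d, noncentral-F design power, parameter-symptom
# correlations.

#' Per-participant acceptance matrix
#'
#' @param records choice records for a single participant (columns
#'   `reward_apples`, `effort_frac`, `accepted`).
#' @return List of class `agt_acceptance`: `matrix` (4 reward x 4 effort
#'   proportions), `counts` (trials per cell), `overall`,
#'   `missing_cells` (labels of empty cells, proportions NA there).
#' @export
acceptance_matrix <- function(records) {
  stopifnot(all(c("reward_apples", "effort_frac", "accepted") %in%
                  names(records)))
  rf <- factor(records$reward_apples, levels = REWARD_LEVELS)
  ef <- factor(records$effort_frac, levels = EFFORT_LEVELS)
  counts <- table(rf, ef)
  acc <- tapply(as.logical(records$accepted), list(rf, ef), mean)
  miss <- which(counts == 0, arr.ind = TRUE)
  missing_cells <- if (nrow(miss))
    paste0(REWARD_LEVELS[miss[, 1]], "apples/",
           100 * EFFORT_LEVELS[miss[, 2]], "%") else character(0)
  structure(list(matrix = acc, counts = unclass(counts),
                 overall = mean(as.logical(records$accepted)),
                 missing_cells = missing_cells),
            class = "agt_acceptance")
}

#' @export
print.agt_acceptance <- function(x, ...) {
  cat("acceptance proportions (reward x effort):\n")
  print(round(x$matrix, 3))
  cat(sprintf("overall: %.3f\n", x$overall))
  if (length(x$missing_cells))
    cat("missing cells:", paste(x$missing_cells, collapse = ", "), "\n")
  invisible(x)
}

# Long records -> participant x 16 cell matrix (reward slow, effort fast)
# plus participant metadata. Errors if any participant has empty cells.
cell_matrix <- function(records) {
  ids <- unique(records$participant_id)
  Y <- matrix(NA_real_, length(ids), 16L,
              dimnames = list(ids, paste0("r", rep(REWARD_LEVELS, each = 4),
                                          "_e", rep(EFFORT_LEVELS, 4))))
  meta <- data.frame(participant_id = ids,
                     group = records$group[match(ids, records$participant_id)],
                     age = records$age[match(ids, records$participant_id)])
  for (i in seq_along(ids)) {
    am <- acceptance_matrix(records[records$participant_id == ids[i], ])
    if (length(am$missing_cells))
      stop_invalid("participant %s has empty design cells: %s", ids[i],
                   paste(am$missing_cells, collapse = ", "))
    Y[i, ] <- as.vector(t(am$matrix))  # reward slow, effort fast
  }
  list(Y = Y, meta = meta)
}

# Orthonormal contrast matrix (k x (k-1)), columns orthonormal and
# orthogonal to the unit vector.
orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Greenhouse-Geisser epsilon and Mauchly test from the error covariance
# S (q x q, already projected through orthonormal within contrasts).
gg_epsilon <- function(S) {
  q <- nrow(S)
  if (q == 1L) return(1)
  tr <- sum(diag(S))
  tr^2 / (q * sum(S * S))
}

mauchly_p <- function(S, df_error) {
  q <- nrow(S)
  if (q == 1L) return(NA_real_)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(0)  # singular: sphericity untenable
  W <- prod(ev) / (mean(ev)^q)
  d <- 1 - (2 * q^2 + q + 2) / (6 * q * df_error)
  stat <- -df_error * d * log(W)
  stats::pchisq(stat, q * (q + 1) / 2 - 1, lower.tail = FALSE)
}

#' Mixed repeated-measures ANOVA on a participant-by-cell matrix
#'
#' General engine behind [rm_anova()]. Rows are participants, columns
#' are the cells of a fully crossed within-subject design (first factor
#' varying slowest). Within effects are tested with the univariate
#' (averaged) F from the multivariate linear model on orthonormal
#' within-subject contrasts; the Greenhouse-Geisser epsilon is estimated
#' from the contrast-projected error covariance, and the corrected p
#' value is reported as primary whenever the Mauchly test rejects
#' sphericity at 0.05. Between effects (group factor with sum-to-zero
#' coding, mean-centred covariate) are tested on the per-participant
#' cell means.
#'
#' @param Y numeric matrix, participants x cells.
#' @param within named integer vector of within-factor level counts,
#'   e.g. `c(reward = 4, effort = 4)`; product must equal `ncol(Y)`.
#' @param group optional participant group labels (length `nrow(Y)`).
#' @param covariate optional numeric covariate, mean-centred internally.
#' @param covariate_name label for the covariate row of the table.
#' @return Object of class `agt_anova`.
#' @export
rm_anova_matrix <- function(Y, within, group = NULL, covariate = NULL,
                            covariate_name = "covariate") {
  stopifnot(is.matrix(Y), !is.null(names(within)), all(within >= 2))
  if (prod(within) != ncol(Y))
    stop_invalid("prod(within) = %d must equal ncol(Y) = %d",
                 prod(within), ncol(Y))
  n <- nrow(Y)
  use_group <- !is.null(group) && length(unique(group)) > 1L
  use_cov <- !is.null(covariate)

  # between-subject design, sum-to-zero group coding, centred covariate
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  term_cols <- list()
  if (use_group) {
    g <- factor(group)
    if (any(table(g) < 2)) stop_invalid("every group needs >= 2 participants")
    Cg <- stats::contr.sum(nlevels(g))
    Xg <- Cg[as.integer(g), , drop = FALSE]
    colnames(Xg) <- paste0("group", seq_len(ncol(Xg)))
    term_cols$group <- ncol(X) + seq_len(ncol(Xg))
    X <- cbind(X, Xg)
  }
  if (use_cov) {
    cv <- covariate - mean(covariate)
    term_cols[[covariate_name]] <- ncol(X) + 1L
    X <- cbind(X, cv)
    colnames(X)[ncol(X)] <- covariate_name
  }
  df_e <- n - ncol(X)
  if (df_e < 1) stop_invalid("too few participants for the design")

  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  E_full <- crossprod(Y - X %*% B)

  # within-subject transformation matrices: for each non-empty subset
  # of within factors, kronecker of orthonormal contrasts (factors in
  # the subset) and normalised unit vectors (factors averaged over)
  nf <- length(within)
  M_list <- list()
  for (mask in seq_len(2^nf - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(nf) - 1)))
    M <- matrix(1, 1, 1)
    for (f in seq_len(nf)) {
      k <- within[f]
      Mf <- if (inset[f]) orth_contrasts(k) else matrix(rep(1 / sqrt(k), k))
      M <- kronecker(M, Mf)
    }
    M_list[[paste(names(within)[inset], collapse = ":")]] <- M
  }
  # conventional ordering: mains first, then interactions
  M_list <- M_list[order(vapply(names(M_list), function(s)
    lengths(regmatches(s, gregexpr(":", s))), integer(1)))]

  hyp_F <- function(M, L) {
    q <- ncol(M); dfh <- nrow(L)
    BM <- B %*% M
    H <- t(L %*% BM) %*% solve(L %*% XtXi %*% t(L)) %*% (L %*% BM)
    S <- t(M) %*% E_full %*% M
    Fv <- (sum(diag(H)) / (q * dfh)) / (sum(diag(S)) / (q * df_e))
    eps <- gg_epsilon(S / df_e)
    list(F = Fv, df1 = q * dfh, df2 = q * df_e, eps = eps,
         p = stats::pf(Fv, q * dfh, q * df_e, lower.tail = FALSE),
         p_gg = stats::pf(Fv, q * dfh * eps, q * df_e * eps,
                          lower.tail = FALSE),
         mauchly = mauchly_p(S / df_e, df_e))
  }
  unit <- function(j) {
    L <- matrix(0, 1, ncol(X)); L[1, j] <- 1; L
  }

  rows <- list()
  add_row <- function(effect, h) {
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, F = h$F, df1 = h$df1, df2 = h$df2, p = h$p,
      epsilon = h$eps %||% NA_real_, df1_gg = h$df1 * (h$eps %||% 1),
      df2_gg = h$df2 * (h$eps %||% 1), p_gg = h$p_gg %||% NA_real_,
      mauchly_p = h$mauchly %||% NA_real_)
  }

  # within main effects + interactions with group (tested on the
  # intercept row / group rows of B respectively)
  for (w in names(M_list)) {
    add_row(w, hyp_F(M_list[[w]], unit(1L)))
    if (use_group) {
      Lg <- matrix(0, length(term_cols$group), ncol(X))
      Lg[cbind(seq_len(nrow(Lg)), term_cols$group)] <- 1
      add_row(paste0(w, ":group"), hyp_F(M_list[[w]], Lg))
    }
  }
  # between effects on the subject means (average over cells)
  ybar <- rowMeans(Y)
  fit_b <- stats::lm.fit(X, ybar)
  sse <- sum(fit_b$residuals^2)
  bhat <- fit_b$coefficients
  for (tn in names(term_cols)) {
    jj <- term_cols[[tn]]
    Lb <- matrix(0, length(jj), ncol(X))
    Lb[cbind(seq_along(jj), jj)] <- 1
    Hb <- t(Lb %*% bhat) %*% solve(Lb %*% XtXi %*% t(Lb)) %*% (Lb %*% bhat)
    Fv <- (Hb / length(jj)) / (sse / df_e)
    rows[[length(rows) + 1L]] <- data.frame(
      effect = tn, F = as.numeric(Fv), df1 = length(jj), df2 = df_e,
      p = stats::pf(Fv, length(jj), df_e, lower.tail = FALSE),
      epsilon = NA_real_, df1_gg = NA_real_, df2_gg = NA_real_,
      p_gg = NA_real_, mauchly_p = NA_real_)
  }
  tab <- do.call(rbind, rows)
  tab$sphericity_violated <- !is.na(tab$mauchly_p) & tab$mauchly_p < 0.05
  tab$p_reported <- ifelse(tab$sphericity_violated, tab$p_gg, tab$p)
  structure(list(table = tab, n = n, transform = "none",
                 between = use_group,
                 covariate = if (use_cov) covariate_name else NULL),
            class = "agt_anova")
}

#' Mixed repeated-measures ANOVA on acceptance rates
#'
#' Within-subject factors reward (4 levels) and effort (4 levels) and
#' their interaction; optional between-subjects group factor and a
#' mean-centred age covariate. Acceptance proportions are arcsine
#' transformed by default before analysis; see [rm_anova_matrix()] for
#' the test construction and the Greenhouse-Geisser/Mauchly handling.
#'
#' @param records long choice-record table with columns
#'   `participant_id`, `reward_apples`, `effort_frac`, `accepted`, and
#'   (if used) `group`, `age`.
#' @param between include the group factor? (default: yes when > 1 group
#'   present).
#' @param covariate name of a covariate column to mean-centre and adjust
#'   for, or NULL.
#' @param transform "arcsine" (default) or "none".
#' @return Object of class `agt_anova`: data frame of effects with F,
#'   df, Greenhouse-Geisser epsilon and corrected df/p, Mauchly p.
#' @export
rm_anova <- function(records, between = NULL, covariate = "age",
                     transform = c("arcsine", "none")) {
  transform <- match.arg(transform)
  cm <- cell_matrix(records)
  Y <- cm$Y
  if (transform == "arcsine") Y <- arcsine_transform(Y)
  meta <- cm$meta
  use_group <- if (is.null(between))
    !all(is.na(meta$group)) && length(unique(meta$group)) > 1L
  else isTRUE(between)
  use_cov <- !is.null(covariate) && covariate %in% names(meta) &&
    !all(is.na(meta[[covariate]]))
  out <- rm_anova_matrix(Y, within = c(reward = 4L, effort = 4L),
                         group = if (use_group) meta$group else NULL,
                         covariate = if (use_cov) meta[[covariate]] else NULL,
                         covariate_name = if (use_cov) covariate else "covariate")
  out$transform <- transform
  out
}

#' @export
print.agt_anova <- function(x, ...) {
  cat(sprintf("repeated-measures ANOVA (%d participants, %s scale%s)\n",
              x$n, if (x$transform == "arcsine") "arcsine" else "raw",
              if (!is.null(x$covariate))
                paste0(", covariate ", x$covariate) else ""))
  tab <- x$table
  out <- data.frame(effect = tab$effect, F = round(tab$F, 3),
                    df1 = round(tab$df1_gg %|na|% tab$df1, 2),
                    df2 = round(tab$df2_gg %|na|% tab$df2, 2),
                    epsilon = round(tab$epsilon, 3),
                    p = signif(tab$p_reported, 4),
                    GG = ifelse(tab$sphericity_violated, "*", ""))
  print(out, row.names = FALSE)
  invisible(x)
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Planned two-sided group contrast
#'
#' Compares two pre-specified pools of groups on a per-participant
#' scalar (e.g. arcsine overall acceptance, or a fitted parameter). The
#' F and p come from a linear model with the optional mean-centred
#' covariate; Cohen's d is computed from the raw (covariate-free) group
#' means with the pooled-sd denominator, sign = first side minus second
#' side.
#'
#' @param values per-participant scalar values.
#' @param group per-participant group labels.
#' @param side1,side2 character vectors of group labels defining the two
#'   sides, e.g. `c("MDD", "REM")` vs `c("REL", "CTR")`.
#' @param covariate optional numeric covariate (e.g. age).
#' @return Object of class `agt_contrast`: d, F, df, p, side sizes.
#' @export
planned_contrast <- function(values, group, side1, side2, covariate = NULL) {
  keep <- group %in% c(side1, side2) & !is.na(values)
  values <- values[keep]; group <- group[keep]
  if (!is.null(covariate)) covariate <- covariate[keep]
  s1 <- group %in% side1; s2 <- group %in% side2
  if (sum(s1) < 2 || sum(s2) < 2)
    stop_invalid("each contrast side needs >= 2 participants")
  m1 <- mean(values[s1]); m2 <- mean(values[s2])
  v1 <- stats::var(values[s1]); v2 <- stats::var(values[s2])
  sp <- sqrt(((sum(s1) - 1) * v1 + (sum(s2) - 1) * v2) /
               (sum(s1) + sum(s2) - 2))
  d <- if (sp == 0) {
    if (m1 == m2) 0 else Inf * sign(m1 - m2)
  } else (m1 - m2) / sp
  side <- factor(ifelse(s1, "side1", "side2"), levels = c("side1", "side2"))
  dat <- data.frame(values = values, side = side)
  fm <- values ~ side
  if (!is.null(covariate)) {
    dat$cov_c <- covariate - mean(covariate)
    fm <- values ~ side + cov_c
  }
  fit <- stats::lm(fm, data = dat)
  an <- stats::anova(fit)
  Fv <- an["side", "F value"]; p <- an["side", "Pr(>F)"]
  df <- c(an["side", "Df"], an["Residuals", "Df"])
  structure(list(d = d, F = Fv, df1 = df[1], df2 = df[2], p = p,
                 n1 = sum(s1), n2 = sum(s2),
                 side1 = side1, side2 = side2,
                 covariate_adjusted = !is.null(covariate)),
            class = "agt_contrast")
}

#' @export
print.agt_contrast <- function(x, ...) {
  cat(sprintf("contrast %s (n=%d) vs %s (n=%d)\n",
              paste(x$side1, collapse = "+"), x$n1,
              paste(x$side2, collapse = "+"), x$n2))
  cat(sprintf("  Cohen's d = %.3f (covariates excluded); F(%d,%d) = %.3f, p = %.4g%s\n",
              x$d, x$df1, x$df2, x$F, x$p,
              if (x$covariate_adjusted) " (covariate-adjusted)" else ""))
  invisible(x)
}

#' Power of the one-way ANOVA omnibus F test
#'
#' Noncentral-F power with noncentrality lambda = f^2 * N, numerator df
#' k - 1 and denominator df N - k, for Cohen's effect size f.
#'
#' @param f Cohen's f effect size (>= 0).
#' @param n vector of group sizes (each >= 2, length = number of groups).
#' @param alpha significance level.
#' @return Power (probability of rejecting the null).
#' @examples
#' anova_power(0.25, c(57, 36, 46, 41))  # about 0.816
#' @export
anova_power <- function(f, n, alpha = 0.05) {
  if (!is.numeric(f) || f < 0) stop_invalid("f must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  if (length(n) < 2 || any(n < 2)) stop_invalid("need >= 2 groups of >= 2")
  N <- sum(n); k <- length(n)
  crit <- stats::qf(1 - alpha, k - 1, N - k)
  stats::pf(crit, k - 1, N - k, ncp = f^2 * N, lower.tail = FALSE)
}

#' Pearson correlation between parameters and symptom factors
#'
#' Listwise-deletes missing pairs, reports r, the t-based two-sided p
#' and the n used. Zero variance in either variable yields r = NA with
#' an explicit flag rather than a silent NaN.
#'
#' @param x,y numeric vectors of equal length.
#' @return List of class `agt_correlation`: r, p, n, n_dropped,
#'   degenerate flag.
#' @export
correlate_params_symptoms <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y) & is.finite(x) & is.finite(y)
  dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_invalid("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, n = length(x),
                          n_dropped = dropped, degenerate = TRUE),
                     class = "agt_correlation"))
  ct <- stats::cor.test(x, y)
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 n_dropped = dropped, degenerate = FALSE),
            class = "agt_correlation")
}

#' @export
print.agt_correlation <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("correlation undefined (zero variance), n = %d\n", x$n))
  else
    cat(sprintf("Pearson r = %.3f, p = %.4g, n = %d%s\n", x$r, x$p, x$n,
                if (x$n_dropped) sprintf(" (%d pairs dropped)", x$n_dropped)
                else ""))
  invisible(x)
}
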