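# Hierarchical estimation of choice-model parameters.
#
# Participant-level parameters theta_i are partially pooled through
# Gaussian group-level distributions theta_ij ~ N(mu_{j,g(i)}, tau_j^2).
# Hyperpriors: mu ~ N(0, 10), tau ~ half-N(0, 5). Group membership
# enters only through the priors, never the likelihood. Two backends:
#
#  * method = "map": EM with a Laplace E-step. Each M-step solves the
#    penalised logistic problem per participant; hypermeans and
#    hypersds have closed-form updates using the Laplace posterior
#    variances (which keeps tau away from the degenerate tau -> 0 joint
#    mode). Posterior draws come from the per-participant Laplace
#    normal approximation.
#  * method = "mcmc": Metropolis-within-Gibbs. Random-walk updates for
#    each participant's parameter block (adapted during warmup), a
#    conjugate Gibbs draw for each hypermean, and a log-scale
#    random-walk for each hypersd. Split-chain R-hat and a simple
#    autocorrelation ESS are reported per quantity.

MU_PRIOR_SD <- 10   # Gaussian hyperprior sd on group means
TAU_PRIOR_SD <- 5   # half-Gaussian hyperprior scale on group sds

# design matrix column for one free parameter of a linear-in-parameters
# spec (additive effort forms)
linear_col <- function(pname, r, e) {
  switch(pname,
         K = rep(1, length(r)), LinR = r, QuadR = r^2, SqrtR = sqrt(r),
         LogR = log1p(r), LinE = e, E2 = e^2,
         stop_invalid("parameter '%s' has no linear design column", pname))
}

is_linear_spec <- function(spec) {
  spec$effort_form %in% c("none", "linear", "quadratic", "linquad")
}

# Build per-participant data structures
prepare_fit_data <- function(records, spec, scaling) {
  need <- c("participant_id", "reward_apples", "effort_frac", "accepted")
  if (!all(need %in% names(records)))
    stop_invalid("records must have columns %s", paste(need, collapse = ", "))
  if (!nrow(records)) stop_invalid("records are empty")
  check_offers(records$reward_apples, records$effort_frac)
  ids <- unique(records$participant_id)
  if (length(ids) < 2) stop_invalid("need records from >= 2 participants")
  r <- scaling$reward_scale(records$reward_apples)
  e <- scaling$effort_scale(records$effort_frac)
  y <- as.numeric(records$accepted)
  pidx <- match(records$participant_id, ids)
  fp <- spec$free_params
  if (!length(fp)) stop_invalid("model '%s' has no free parameters", spec$name)
  lin <- is_linear_spec(spec)
  X <- NULL; offset <- rep(0, nrow(records))
  if (lin) {
    X <- vapply(fp, linear_col, numeric(nrow(records)), r = r, e = e)
    if (length(spec$constraints))
      for (cn in names(spec$constraints))
        offset <- offset + spec$constraints[[cn]] * linear_col(cn, r, e)
  }
  grp <- if ("group" %in% names(records))
    records$group[match(ids, records$participant_id)] else rep("all", length(ids))
  list(ids = ids, n = length(ids), pidx = pidx, y = y, r = r, e = e,
       X = X, offset = offset, linear = lin, free = fp, p = length(fp),
       group = as.character(grp), spec = spec)
}

# prior-group index per (participant, parameter) under a scheme
prior_groups <- function(dat, scheme, param_of_interest) {
  gf <- factor(dat$group)
  G <- nlevels(gf)
  map <- matrix(1L, dat$n, dat$p,
                dimnames = list(NULL, dat$free))
  ngroups <- stats::setNames(rep(1L, dat$p), dat$free)
  per_group_params <- switch(scheme,
    shared = character(0),
    per_group = {
      if (is.null(param_of_interest) ||
          !param_of_interest %in% dat$free)
        stop_invalid("scheme 'per_group' needs param_of_interest among free parameters (%s)",
                     paste(dat$free, collapse = ", "))
      param_of_interest
    },
    per_group_all = dat$free)
  if (length(per_group_params) && G < 2 && scheme != "shared") {
    # single group: per-group priors degenerate to shared
    per_group_params <- if (G >= 2) per_group_params else per_group_params
  }
  for (pp in per_group_params) {
    map[, pp] <- as.integer(gf)
    ngroups[pp] <- G
  }
  list(map = map, ngroups = ngroups, levels = levels(gf))
}

# participant log-likelihood given theta matrix (n x p); returns vector n
cohort_loglik <- function(dat, theta, pointwise = FALSE) {
  if (dat$linear) {
    v <- rowSums(dat$X * theta[dat$pidx, , drop = FALSE]) + dat$offset
  } else {
    v <- numeric(length(dat$y))
    for (i in seq_len(dat$n)) {
      rows <- dat$pidx == i
      full <- full_param_vector(dat$spec,
                                stats::setNames(theta[i, ], dat$free))
      v[rows] <- model_value_scaled(dat$spec, full, dat$r[rows], dat$e[rows])
    }
  }
  pw <- ifelse(dat$y == 1, stats::plogis(v, log.p = TRUE),
               stats::plogis(-v, log.p = TRUE))
  if (pointwise) return(pw)
  as.numeric(rowsum(pw, dat$pidx))
}

# --- MAP backend ---------------------------------------------------------

# penalised fit for one participant; returns list(theta, var, hess)
map_participant <- function(dat, i, mu_i, tau_i, start) {
  prior_prec <- 1 / tau_i^2
  if (dat$linear) {
    rows <- which(dat$pidx == i)
    X <- dat$X[rows, , drop = FALSE]
    y <- dat$y[rows]; off <- dat$offset[rows]
    th <- start
    for (it in 1:50) {  # Newton with step halving
      eta <- drop(X %*% th) + off
      p <- stats::plogis(eta)
      g <- drop(crossprod(X, y - p)) - (th - mu_i) * prior_prec
      W <- p * (1 - p)
      H <- crossprod(X * W, X) + diag(prior_prec, dat$p)
      step <- solve(H, g)
      obj0 <- sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                         stats::plogis(-eta, log.p = TRUE))) -
        sum((th - mu_i)^2 * prior_prec) / 2
      alpha <- 1
      repeat {
        th_new <- th + alpha * step
        eta_n <- drop(X %*% th_new) + off
        obj <- sum(ifelse(y == 1, stats::plogis(eta_n, log.p = TRUE),
                          stats::plogis(-eta_n, log.p = TRUE))) -
          sum((th_new - mu_i)^2 * prior_prec) / 2
        if (obj >= obj0 - 1e-12 || alpha < 1e-4) break
        alpha <- alpha / 2
      }
      moved <- max(abs(th_new - th))
      th <- th_new
      if (moved < 1e-8) break
    }
    eta <- drop(X %*% th) + off
    W <- stats::plogis(eta) * (1 - stats::plogis(eta))
    H <- crossprod(X * W, X) + diag(prior_prec, dat$p)
    list(theta = th, cov = solve(H))
  } else {
    rows <- which(dat$pidx == i)
    nll <- function(th) {
      full <- full_param_vector(dat$spec, stats::setNames(th, dat$free))
      v <- model_value_scaled(dat$spec, full, dat$r[rows], dat$e[rows])
      pw <- ifelse(dat$y[rows] == 1, stats::plogis(v, log.p = TRUE),
                   stats::plogis(-v, log.p = TRUE))
      -(sum(pw) - sum((th - mu_i)^2 * prior_prec) / 2)
    }
    opt <- stats::optim(start, nll, method = "BFGS",
                        control = list(maxit = 200))
    H <- stats::optimHess(opt$par, nll)
    cov <- tryCatch(solve(H), error = function(e) {
      solve(H + diag(1e-6, dat$p))
    })
    list(theta = opt$par, cov = cov)
  }
}

# pooled single-set estimate across all participants: initialises the
# EM near the likelihood ridge instead of at zero
pooled_start <- function(dat) {
  if (dat$linear) {
    th <- rep(0, dat$p)
    for (it in 1:30) {
      eta <- drop(dat$X %*% th) + dat$offset
      pr <- stats::plogis(eta)
      g <- drop(crossprod(dat$X, dat$y - pr)) - th / 100
      H <- crossprod(dat$X * (pr * (1 - pr)), dat$X) + diag(1 / 100, dat$p)
      step <- solve(H, g)
      th <- th + step
      if (max(abs(step)) < 1e-6) break
    }
    th
  } else {
    nll <- function(th) {
      full <- full_param_vector(dat$spec, stats::setNames(th, dat$free))
      v <- model_value_scaled(dat$spec, full, dat$r, dat$e)
      -sum(ifelse(dat$y == 1, stats::plogis(v, log.p = TRUE),
                  stats::plogis(-v, log.p = TRUE))) + sum(th^2) / 200
    }
    stats::optim(rep(0, dat$p), nll, method = "BFGS",
                 control = list(maxit = 200))$par
  }
}

fit_map <- function(dat, pg, ndraws, loglik_draws, seed, maxit = 200,
                    tol = 1e-4, verbose = FALSE) {
  n <- dat$n; p <- dat$p
  start <- pooled_start(dat)
  theta <- matrix(rep(start, each = n), n, p,
                  dimnames = list(dat$ids, dat$free))
  vars <- matrix(1, n, p)
  covs <- vector("list", n)
  mu <- lapply(seq_len(p), function(j) rep(start[j], pg$ngroups[j]))
  tau <- lapply(seq_len(p), function(j) rep(2, pg$ngroups[j]))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    theta_old <- theta
    for (i in seq_len(n)) {
      mu_i <- vapply(seq_len(p), function(j) mu[[j]][pg$map[i, j]],
                     numeric(1))
      tau_i <- vapply(seq_len(p), function(j) tau[[j]][pg$map[i, j]],
                      numeric(1))
      res <- map_participant(dat, i, mu_i, tau_i, theta[i, ])
      theta[i, ] <- res$theta
      vars[i, ] <- pmax(diag(res$cov), 0)
      covs[[i]] <- res$cov
    }
    for (j in seq_len(p)) {
      for (g in seq_len(pg$ngroups[j])) {
        sel <- pg$map[, j] == g
        ng <- sum(sel)
        # hypermean: normal-normal with N(0, MU_PRIOR_SD^2)
        prec <- ng / tau[[j]][g]^2 + 1 / MU_PRIOR_SD^2
        mu[[j]][g] <- sum(theta[sel, j]) / tau[[j]][g]^2 / prec
        # hypersd: mode of half-normal prior x normal model, using
        # E[(theta - mu)^2] = (thetahat - mu)^2 + Laplace var
        S <- sum((theta[sel, j] - mu[[j]][g])^2 + vars[sel, j])
        a <- 1 / TAU_PRIOR_SD^2
        tau2 <- (-ng + sqrt(ng^2 + 4 * a * S)) / (2 * a)
        tau[[j]][g] <- sqrt(max(tau2, 1e-6))
      }
    }
    delta <- max(abs(theta - theta_old))
    if (verbose) message(sprintf("EM iter %d: max|dtheta| = %.2e", it, delta))
    if (delta < tol) { converged <- TRUE; break }
  }
  # Laplace draws
  draws <- with_seed(child_seed(seed, 7919L), {
    arr <- array(NA_real_, c(ndraws, n, p),
                 dimnames = list(NULL, dat$ids, dat$free))
    for (i in seq_len(n)) {
      R <- tryCatch(chol(covs[[i]]), error = function(e)
        chol(covs[[i]] + diag(1e-8, p)))
      Z <- matrix(stats::rnorm(ndraws * p), ndraws, p)
      arr[, i, ] <- rep(theta[i, ], each = ndraws) + Z %*% R
    }
    arr
  })
  hyper <- hyper_table(dat, pg, mu, tau)
  list(theta_mean = theta, theta_sd = sqrt(vars), draws = draws,
       hyper = hyper, mu = mu, tau = tau, converged = converged,
       iterations = it, rhat = NULL)
}

hyper_table <- function(dat, pg, mu, tau, mu_sd = NULL) {
  rows <- list()
  for (j in seq_len(dat$p)) {
    for (g in seq_len(pg$ngroups[j])) {
      sel <- pg$map[, j] == g
      ng <- sum(sel)
      prec <- ng / tau[[j]][g]^2 + 1 / MU_PRIOR_SD^2
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = dat$free[j],
        group = if (pg$ngroups[j] > 1) pg$levels[g] else "all",
        mean = mu[[j]][g],
        mean_sd = if (is.null(mu_sd)) sqrt(1 / prec) else mu_sd[[j]][g],
        sd = tau[[j]][g], n = ng)
    }
  }
  do.call(rbind, rows)
}

# --- MCMC backend --------------------------------------------------------

fit_mcmc <- function(dat, pg, chains, iter, warmup, loglik_draws, seed,
                     verbose = FALSE) {
  n <- dat$n; p <- dat$p
  total <- warmup + iter
  keep_theta <- array(NA_real_, c(iter, chains, n, p))
  keep_mu <- array(NA_real_, c(iter, chains, p, max(pg$ngroups)))
  keep_tau <- array(NA_real_, c(iter, chains, p, max(pg$ngroups)))
  for (ch in seq_len(chains)) {
    with_seed(child_seed(seed, 104729L + ch), {
      theta <- matrix(stats::rnorm(n * p, 0, 0.5), n, p)
      mu <- lapply(seq_len(p), function(j) rep(0, pg$ngroups[j]))
      tau <- lapply(seq_len(p), function(j) rep(2, pg$ngroups[j]))
      scale_i <- matrix(0.3, n, p)
      acc_count <- matrix(0, n, p)
      ll <- cohort_loglik(dat, theta)
      for (t in seq_len(total)) {
        # per-participant random-walk block update
        prop <- theta + scale_i * matrix(stats::rnorm(n * p), n, p)
        ll_prop <- cohort_loglik(dat, prop)
        lpr <- numeric(n); lpr_prop <- numeric(n)
        for (j in seq_len(p)) {
          m <- mu[[j]][pg$map[, j]]; s <- tau[[j]][pg$map[, j]]
          lpr <- lpr + stats::dnorm(theta[, j], m, s, log = TRUE)
          lpr_prop <- lpr_prop + stats::dnorm(prop[, j], m, s, log = TRUE)
        }
        acc <- log(stats::runif(n)) < (ll_prop + lpr_prop - ll - lpr)
        theta[acc, ] <- prop[acc, , drop = FALSE]
        ll[acc] <- ll_prop[acc]
        acc_count[acc, ] <- acc_count[acc, ] + 1
        if (t <= warmup && t %% 50 == 0) {
          rate <- acc_count / 50
          scale_i <- scale_i * exp((rate - 0.30))
          scale_i <- pmin(pmax(scale_i, 1e-3), 10)
          acc_count[] <- 0
        }
        # hypermeans: conjugate Gibbs
        for (j in seq_len(p)) for (g in seq_len(pg$ngroups[j])) {
          sel <- pg$map[, j] == g
          prec <- sum(sel) / tau[[j]][g]^2 + 1 / MU_PRIOR_SD^2
          m <- sum(theta[sel, j]) / tau[[j]][g]^2 / prec
          mu[[j]][g] <- stats::rnorm(1, m, sqrt(1 / prec))
        }
        # hypersds: random walk on log tau, half-normal prior
        for (j in seq_len(p)) for (g in seq_len(pg$ngroups[j])) {
          sel <- pg$map[, j] == g
          lt <- log(tau[[j]][g]); lt_p <- lt + stats::rnorm(1, 0, 0.2)
          t0 <- tau[[j]][g]; t1 <- exp(lt_p)
          dev <- theta[sel, j] - mu[[j]][pg$map[sel, j][1]]
          lp0 <- sum(stats::dnorm(dev, 0, t0, log = TRUE)) -
            t0^2 / (2 * TAU_PRIOR_SD^2) + lt
          lp1 <- sum(stats::dnorm(dev, 0, t1, log = TRUE)) -
            t1^2 / (2 * TAU_PRIOR_SD^2) + lt_p
          if (log(stats::runif(1)) < lp1 - lp0) tau[[j]][g] <- t1
        }
        if (t > warmup) {
          k <- t - warmup
          keep_theta[k, ch, , ] <- theta
          for (j in seq_len(p)) {
            keep_mu[k, ch, j, seq_len(pg$ngroups[j])] <- mu[[j]]
            keep_tau[k, ch, j, seq_len(pg$ngroups[j])] <- tau[[j]]
          }
        }
      }
    })
    if (verbose) message(sprintf("chain %d/%d done", ch, chains))
  }
  # pool chains
  nd <- iter * chains
  draws <- array(aperm(keep_theta, c(1, 2, 3, 4)), c(nd, n, p),
                 dimnames = list(NULL, dat$ids, dat$free))
  theta_mean <- apply(draws, c(2, 3), mean)
  theta_sd <- apply(draws, c(2, 3), stats::sd)
  mu_hat <- lapply(seq_len(p), function(j)
    vapply(seq_len(pg$ngroups[j]), function(g)
      mean(keep_mu[, , j, g]), numeric(1)))
  mu_sd <- lapply(seq_len(p), function(j)
    vapply(seq_len(pg$ngroups[j]), function(g)
      stats::sd(as.vector(keep_mu[, , j, g])), numeric(1)))
  tau_hat <- lapply(seq_len(p), function(j)
    vapply(seq_len(pg$ngroups[j]), function(g)
      mean(keep_tau[, , j, g]), numeric(1)))
  # diagnostics: split-chain R-hat over hyper quantities + participant
  # parameters
  rhat_rows <- list()
  for (j in seq_len(p)) for (g in seq_len(pg$ngroups[j])) {
    rhat_rows[[length(rhat_rows) + 1L]] <- data.frame(
      quantity = sprintf("mu[%s,%d]", dat$free[j], g),
      rhat = split_rhat(keep_mu[, , j, g, drop = FALSE][, , 1, 1]),
      ess = ess_basic(keep_mu[, , j, g, drop = FALSE][, , 1, 1]))
    rhat_rows[[length(rhat_rows) + 1L]] <- data.frame(
      quantity = sprintf("tau[%s,%d]", dat$free[j], g),
      rhat = split_rhat(keep_tau[, , j, g, drop = FALSE][, , 1, 1]),
      ess = ess_basic(keep_tau[, , j, g, drop = FALSE][, , 1, 1]))
  }
  for (i in seq_len(n)) for (j in seq_len(p)) {
    rhat_rows[[length(rhat_rows) + 1L]] <- data.frame(
      quantity = sprintf("theta[%s,%s]", dat$ids[i], dat$free[j]),
      rhat = split_rhat(keep_theta[, , i, j]),
      ess = ess_basic(keep_theta[, , i, j]))
  }
  rhat <- do.call(rbind, rhat_rows)
  hyper <- hyper_table(dat, pg, mu_hat, tau_hat, mu_sd = mu_sd)
  list(theta_mean = theta_mean, theta_sd = theta_sd, draws = draws,
       hyper = hyper, mu = mu_hat, tau = tau_hat, converged = TRUE,
       iterations = total, rhat = rhat)
}

# split-chain R-hat; x is iter x chains
split_rhat <- function(x) {
  x <- as.matrix(x)
  half <- floor(nrow(x) / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[half + seq_len(half), , drop = FALSE])
  m <- ncol(xs); nn <- nrow(xs)
  cm <- colMeans(xs)
  B <- nn * stats::var(cm)
  W <- mean(apply(xs, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# crude autocorrelation-based ESS, pooled over chains
ess_basic <- function(x) {
  x <- as.matrix(x)
  nn <- nrow(x); m <- ncol(x)
  rho_sum <- 0
  for (ch in seq_len(m)) {
    v <- x[, ch]
    if (stats::sd(v) == 0) next
    ac <- stats::acf(v, lag.max = min(100, nn - 2), plot = FALSE)$acf[-1]
    pos <- which(ac < 0.05)
    cut <- if (length(pos)) pos[1] - 1 else length(ac)
    rho_sum <- rho_sum + sum(ac[seq_len(cut)])
  }
  rho <- rho_sum / m
  max(1, (nn * m) / (1 + 2 * max(rho, 0)))
}

# --- main fitting function ----------------------------------------------

#' Fit a hierarchical choice model to AGT records
#'
#' Participant-level parameters of the given subjective-value model are
#' estimated with partial pooling: each free parameter is drawn from a
#' Gaussian group-level distribution whose mean and sd carry N(0, 10)
#' and half-N(0, 5) hyperpriors. The prior scheme controls how group
#' labels enter: `"shared"` pools everyone under one prior;
#' `"per_group"` gives the single `param_of_interest` separate
#' group-level priors (one parameter at a time) while all other
#' parameters stay shared; `"per_group_all"` separates every parameter
#' (the sensitivity-analysis configuration). Group membership never
#' enters the likelihood.
#'
#' @param records long choice-record table (columns `participant_id`,
#'   `reward_apples`, `effort_frac`, `accepted`; `group` for per-group
#'   schemes).
#' @param model an [agt_model_spec()] (default: Pilot winning model).
#' @param scheme prior scheme (see above).
#' @param param_of_interest parameter name for `scheme = "per_group"`.
#' @param method `"map"` (EM + Laplace draws; fast, deterministic point
#'   estimates) or `"mcmc"` (Metropolis-within-Gibbs).
#' @param chains,iter,warmup MCMC settings (kept draws per chain =
#'   `iter`).
#' @param ndraws_map number of Laplace draws in MAP mode.
#' @param loglik_draws maximum posterior draws used for the stored
#'   pointwise log-likelihood matrix (thinned if needed).
#' @param seed integer seed.
#' @param scaling an [agt_scaling()] object.
#' @param verbose print progress?
#' @return An object of class `agt_fit`; see [summary.agt_fit()],
#'   [coef.agt_fit()], [predict.agt_fit()],
#'   [posterior_predictive_acceptance()].
#' @export
fit_agt <- function(records, model = winning_model("pilot"),
                    scheme = c("shared", "per_group", "per_group_all"),
                    param_of_interest = NULL,
                    method = c("map", "mcmc"),
                    chains = 4L, iter = 1000L, warmup = 1000L,
                    ndraws_map = 400L, loglik_draws = 400L,
                    seed = 1L, scaling = agt_scaling(), verbose = FALSE) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  stopifnot(inherits(model, "agt_model"))
  dat <- prepare_fit_data(records, model, scaling)
  if (scheme != "shared" && !"group" %in% names(records))
    stop_invalid("scheme '%s' requires a group column", scheme)
  pg <- prior_groups(dat, scheme, param_of_interest)
  res <- if (method == "map")
    fit_map(dat, pg, ndraws = ndraws_map, loglik_draws = loglik_draws,
            seed = seed, verbose = verbose)
  else
    fit_mcmc(dat, pg, chains = chains, iter = iter, warmup = warmup,
             loglik_draws = loglik_draws, seed = seed, verbose = verbose)
  # pointwise log-likelihood over (thinned) draws
  nd <- dim(res$draws)[1]
  keep <- if (nd > loglik_draws)
    round(seq(1, nd, length.out = loglik_draws)) else seq_len(nd)
  pw <- matrix(NA_real_, length(keep), length(dat$y))
  for (k in seq_along(keep)) {
    th <- matrix(res$draws[keep[k], , ], dat$n, dat$p)
    pw[k, ] <- cohort_loglik(dat, th, pointwise = TRUE)
  }
  max_rhat <- if (!is.null(res$rhat)) max(res$rhat$rhat, na.rm = TRUE) else NA
  if (!is.na(max_rhat) && max_rhat > 1.05)
    warning(sprintf("convergence diagnostic above threshold: max R-hat = %.3f",
                    max_rhat), call. = FALSE)
  out <- list(model = model, scheme = scheme,
              param_of_interest = param_of_interest, method = method,
              seed = as.integer(seed), scaling = scaling,
              participants = data.frame(participant_id = dat$ids,
                                        group = dat$group),
              theta_mean = res$theta_mean, theta_sd = res$theta_sd,
              draws = res$draws, hyper = res$hyper,
              pointwise_ll = pw, records = records,
              checksum = records_checksum(records),
              diagnostics = list(rhat = res$rhat, max_rhat = max_rhat,
                                 converged = res$converged,
                                 iterations = res$iterations),
              config = list(method = method, chains = chains, iter = iter,
                            warmup = warmup, ndraws_map = ndraws_map,
                            loglik_draws = loglik_draws))
  class(out) <- "agt_fit"
  out
}
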