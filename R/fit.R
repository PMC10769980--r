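# Hierarchical Bayesian estimation for the three designs. Each fit models
# trial-level Bernoulli responses through the design's psychometric family,
# with participant-level parameters drawn from population distributions
# (generalised linear mixed models on the log-spread / equivalent-noise /
# log-threshold scales), and returns posterior draws plus derived effect
# ratios as an `en_fit` object.

# Condition-level design matrix: intercept, two-level factor (absent /
# incongruent coded +1/2 so exp(beta) is the absent-vs-present ratio),
# linear set-size-rank trend coded -1/0/+1 (exp(beta) is the factor per
# increment in set-size condition), quadratic trend (1,-2,1)/3, and the
# factor x trend interactions.
.design_matrix <- function(conditions, factor_col) {
  rank <- match(conditions$set_size, sort(unique(conditions$set_size)))
  lin <- c(-1, 0, 1)[rank]
  quad <- c(1, -2, 1)[rank] / 3
  fac <- ifelse(conditions[[factor_col]], -0.5, 0.5)  # TRUE = baseline level
  X <- cbind(intercept = 1, fac = fac, lin = lin, quad = quad,
             fac_lin = fac * lin, fac_quad = fac * quad)
  rownames(X) <- conditions$condition
  X
}

#' Prior specification for the hierarchical fits
#'
#' Weakly informative priors chosen so that prior-predictive psychometric
#' parameters stay inside the stimulus-resolvable range (see the methods
#' vignette): population intercepts Normal(log 8, 0.85) for log-spread,
#' Normal(log 6, 0.85) for log internal noise, Normal(log 0.06, 0.85) for
#' log-threshold, Normal(0, 10) for midpoints (degrees); effect
#' coefficients Normal(0, 0.35) on log scales and Normal(0, 2) for midpoint
#' effects (degrees); random-effect scales half-Normal(0.5) (log scales)
#' and half-Normal(2) (degrees); integration exponent x = 1.25 * plogis(eta)
#' with eta Normal(0, 1.5).
#'
#' @param experiment 1, 2 or 3.
#' @return list with `mu0`, `sd0`, `re_scale0`, `names`, and (experiment 3)
#'   the shared-lapse prior.
#' @export
en_priors <- function(experiment) {
  switch(as.character(experiment),
    "1" = list(
      names = c(paste0("spread_", c("intercept", "shadow_absent", "lin",
                                    "quad", "shadow_lin", "shadow_quad")),
                paste0("mid_", c("intercept", "shadow_absent", "lin",
                                 "quad", "shadow_lin", "shadow_quad"))),
      mu0 = c(log(8), rep(0, 5), rep(0, 6)),
      sd0 = c(0.85, rep(0.35, 5), 10, rep(2, 5)),
      re_scale0 = c(rep(0.5, 6), 2, rep(1, 5))),
    "2" = list(
      names = c("log_sigma_int", "eta_exponent", "midpoint"),
      mu0 = c(log(6), 0, 0),
      sd0 = c(0.85, 1.5, 10),
      re_scale0 = c(0.5, 0.5, 2)),
    "3" = list(
      names = c(paste0("thr_", c("intercept", "incongruent", "lin", "quad",
                                 "incongruent_lin", "incongruent_quad")),
                "log_slope"),
      mu0 = c(log(0.06), rep(0, 5), log(3)),
      sd0 = c(0.85, rep(0.35, 5), 0.5),
      re_scale0 = c(rep(0.5, 6), 0.5),
      lapse_prior = c(mean = stats::qlogis(0.04), sd = 1)),
    stop("'experiment' must be 1, 2 or 3"))
}

.split_log <- function(log, experiment, need_cols) {
  log <- log[log$experiment == experiment, , drop = FALSE]
  if (nrow(log) == 0) stop("no experiment-", experiment, " trials in log")
  split(log[, need_cols, drop = FALSE], log$participant)
}

.check_conditions <- function(log, conditions) {
  tab <- table(log$participant, log$condition)
  if (any(tab[, as.character(conditions$condition), drop = FALSE] == 0)) {
    stop("every participant must contribute trials to all ",
         nrow(conditions), " conditions")
  }
}

.new_en_fit <- function(experiment, mcmc, priors, participants, extra) {
  diag_draws <- cbind(mcmc$mu, mcmc$s)
  colnames(diag_draws) <- c(paste0("mu_", priors$names),
                            paste0("s_", priors$names))
  if (!is.null(mcmc$shared)) diag_draws <- cbind(diag_draws, mcmc$shared)
  diagnostics <- mcmc_diagnostics(diag_draws, mcmc$chain)
  structure(c(list(experiment = experiment,
                   theta = mcmc$theta, mu = mcmc$mu, s = mcmc$s,
                   shared = mcmc$shared, chain = mcmc$chain, lp = mcmc$lp,
                   accept = mcmc$accept,
                   param_names = priors$names,
                   participants = participants,
                   diagnostics = diagnostics,
                   converged = !isTRUE(attr(diagnostics, "flagged"))),
              extra),
            class = "en_fit")
}

#' Fit the set-size x cast-shadows direction-discrimination model
#'
#' Bernoulli likelihood of rightwards judgements through a cumulative
#' Normal psychometric function with a fixed small lapse. Log-spread and
#' midpoint each get the full condition design (intercept, cast-shadows
#' main effect, linear and quadratic set-size-rank trends, interactions)
#' with participant-level deviations on every coefficient.
#'
#' @param log trial-log data.frame (experiment-1 schema).
#' @param lapse fixed lapse rate of the response model (default 0.01).
#' @param n_warmup,n_save,thin,chains,seed MCMC controls (see [hier_mwg()]).
#' @return an `en_fit`.
#' @export
fit_exp1 <- function(log, lapse = 0.01, n_warmup = 800, n_save = 800,
                     thin = 2, chains = 4, seed = 1) {
  conditions <- exp_config(1)$conditions
  .check_conditions(log[log$experiment == 1, ], conditions)
  X <- .design_matrix(conditions, "shadows")
  by_p <- .split_log(log, 1L, c("mean_angle", "response", "condition"))
  data <- lapply(by_p, function(d) list(
    angle = d$mean_angle, y = as.numeric(d$response == "right"),
    cond = match(d$condition, conditions$condition)))
  loglik <- function(theta, shared, d) {
    spread <- exp(X %*% theta[1:6])
    mid <- X %*% theta[7:12]
    p <- pf_cnorm(d$angle, mid[d$cond], spread[d$cond], lapse)
    sum(d$y * log(p) + (1 - d$y) * log1p(-p))
  }
  pr <- en_priors(1)
  mcmc <- hier_mwg(data, loglik, K = 12, mu0 = pr$mu0, sd0 = pr$sd0,
                   re_scale0 = pr$re_scale0, n_warmup = n_warmup,
                   n_save = n_save, thin = thin, chains = chains,
                   seed = seed)
  .new_en_fit(1L, mcmc, pr, names(data),
              list(X = X, conditions = conditions, lapse = lapse,
                   data = data, log = log))
}

#' Fit the equivalent-noise integration model
#'
#' Bernoulli likelihood of rightwards judgements through a wrapped
#' cumulative Normal whose spread follows the equivalent-noise law
#' sigma = sqrt((sigma_int^2 + sigma_ext^2) / N) with N = set_size^x.
#' Per participant: log internal noise, integration exponent
#' (x = 1.25 plogis(eta)), and midpoint, each drawn from population
#' distributions. When the log contains no external-noise trials the
#' internal noise and exponent are not jointly identifiable; the fit then
#' warns and flags itself as degenerate.
#'
#' @inheritParams fit_exp1
#' @return an `en_fit`.
#' @export
fit_exp2 <- function(log, lapse = 0.01, n_warmup = 1000, n_save = 1000,
                     thin = 2, chains = 4, seed = 1) {
  conditions <- exp_config(2)$conditions
  sub <- log[log$experiment == 2, ]
  if (length(unique(sub$set_size)) < 2) {
    stop("both set-size conditions must be present")
  }
  by_p <- .split_log(log, 2L, c("mean_angle", "ext_noise_sd", "set_size",
                                "response"))
  data <- lapply(by_p, function(d) list(
    angle = d$mean_angle, ext = d$ext_noise_sd, ss = d$set_size,
    y = as.numeric(d$response == "right")))
  degenerate <- all(sub$ext_noise_sd == 0)
  if (degenerate) {
    warning("all trials have zero external noise: sigma_int and the ",
            "integration exponent are not jointly identifiable")
  }
  loglik <- function(theta, shared, d) {
    si <- exp(theta[1])
    x <- 1.25 * stats::plogis(theta[2])
    spread <- en_spread(si, d$ext, pmax(1, d$ss^x))
    p <- pf_wrapped_cnorm(d$angle, theta[3], spread, lapse)
    sum(d$y * log(p) + (1 - d$y) * log1p(-p))
  }
  pr <- en_priors(2)
  mcmc <- hier_mwg(data, loglik, K = 3, mu0 = pr$mu0, sd0 = pr$sd0,
                   re_scale0 = pr$re_scale0, n_warmup = n_warmup,
                   n_save = n_save, thin = thin, chains = chains,
                   seed = seed)
  fit <- .new_en_fit(2L, mcmc, pr, names(data),
                     list(conditions = conditions, lapse = lapse,
                          data = data, log = log, degenerate = degenerate))
  if (degenerate) fit$converged <- FALSE
  fit
}

#' Fit the shape-identification threshold model
#'
#' Bernoulli likelihood of correct 2AFC responses through a Weibull
#' psychometric function with guess rate 0.5 and an estimated lapse shared
#' across participants. Log-threshold gets the full condition design
#' (intercept, illumination-incongruence effect, set-size trends,
#' interactions) with participant deviations; the log-slope is a
#' participant-level parameter with its own population distribution.
#'
#' @inheritParams fit_exp1
#' @return an `en_fit`.
#' @export
fit_exp3 <- function(log, n_warmup = 800, n_save = 800, thin = 2,
                     chains = 4, seed = 1) {
  conditions <- exp_config(3)$conditions
  .check_conditions(log[log$experiment == 3, ], conditions)
  X <- .design_matrix(conditions, "congruent")
  by_p <- .split_log(log, 3L, c("amplitude", "correct", "condition"))
  data <- lapply(by_p, function(d) list(
    amp = d$amplitude, y = as.numeric(d$correct),
    cond = match(d$condition, conditions$condition)))
  loglik <- function(theta, shared, d) {
    alpha <- exp(X %*% theta[1:6])
    beta <- exp(theta[7])
    lam <- 0.5 * stats::plogis(shared[1])
    p <- pf_weibull(d$amp, alpha[d$cond], beta, 0.5, lam)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(d$y * log(p) + (1 - d$y) * log1p(-p))
  }
  pr <- en_priors(3)
  mcmc <- hier_mwg(data, loglik, K = 7, mu0 = pr$mu0, sd0 = pr$sd0,
                   re_scale0 = pr$re_scale0,
                   shared_init = c(logit_lapse = pr$lapse_prior[["mean"]]),
                   shared_prior_mean = pr$lapse_prior[["mean"]],
                   shared_prior_sd = pr$lapse_prior[["sd"]],
                   n_warmup = n_warmup, n_save = n_save, thin = thin,
                   chains = chains, seed = seed)
  .new_en_fit(3L, mcmc, pr, names(data),
              list(X = X, conditions = conditions, data = data, log = log))
}

#' Fast per-participant point estimates for the equivalent-noise model
#'
#' Maximum a posteriori estimates of (internal noise, integration exponent,
#' midpoint) per participant, by direct optimisation of the wrapped-Normal
#' equivalent-noise likelihood plus the population-level priors of
#' [en_priors()] (the weak priors regularise directions the likelihood
#' leaves flat, e.g. small internal noise). Returned in the `en_fit` layout
#' with a
#' single plug-in "draw", so it can stand in for the full posterior in
#' screening (internal-noise exclusion) and residual analyses where speed
#' matters more than uncertainty.
#'
#' @param log trial-log data.frame (experiment-2 schema).
#' @param lapse fixed lapse of the response model.
#' @return an `en_fit` with one draw (`pointwise = TRUE`).
#' @export
fit_en_pointwise <- function(log, lapse = 0.01) {
  by_p <- .split_log(log, 2L, c("mean_angle", "ext_noise_sd", "set_size",
                                "response"))
  pr <- en_priors(2)
  P <- length(by_p)
  theta <- array(NA_real_, c(1, P, 3))
  for (p in seq_len(P)) {
    d <- by_p[[p]]
    y <- as.numeric(d$response == "right")
    nll <- function(th) {
      si <- exp(th[1]); x <- 1.25 * stats::plogis(th[2])
      pp <- pf_wrapped_cnorm(d$mean_angle, th[3],
                             en_spread(si, d$ext_noise_sd,
                                       pmax(1, d$set_size^x)), lapse)
      -sum(y * log(pp) + (1 - y) * log1p(-pp)) -
        sum(stats::dnorm(th, pr$mu0, pr$sd0, log = TRUE))
    }
    opt <- stats::optim(c(log(6), 0, 0), nll, method = "Nelder-Mead",
                        control = list(maxit = 500))
    theta[1, p, ] <- opt$par
  }
  # diagnostics are meaningless for a single plug-in draw
  fit <- structure(list(experiment = 2L, theta = theta,
                        mu = matrix(apply(theta[1, , , drop = FALSE], 3, mean), 1, 3),
                        s = matrix(0, 1, 3), shared = NULL, chain = 1L,
                        lp = 0, accept = NA_real_,
                        param_names = pr$names,
                        participants = names(by_p),
                        diagnostics = NULL, converged = NA,
                        conditions = exp_config(2)$conditions,
                        lapse = lapse, data = NULL, log = log,
                        degenerate = FALSE, pointwise = TRUE),
                   class = "en_fit")
  fit
}

#' Per-participant internal-noise estimates from a fit
#'
#' Posterior medians (or plug-in values) of internal noise in degrees,
#' named by participant - the quantity screened by the exclusion rule.
#'
#' @param fit an `en_fit` from [fit_exp2()] or [fit_en_pointwise()].
#' @return named numeric vector.
#' @export
sigma_int_estimates <- function(fit) {
  stopifnot(inherits(fit, "en_fit"), fit$experiment == 2L)
  est <- apply(exp(fit$theta[, , 1, drop = FALSE]), 2, stats::median)
  names(est) <- fit$participants
  est
}

#' @export
print.en_fit <- function(x, ...) {
  nd <- dim(x$theta)[1]
  cat(sprintf("<en_fit> experiment %d: %d participant(s), %d draws%s\n",
              x$experiment, length(x$participants), nd,
              if (isTRUE(x$pointwise)) " (plug-in point estimates)"
              else if (isTRUE(x$converged)) ""
              else " [convergence flagged]"))
  invisible(x)
}

#' Posterior draws of the derived effect quantities
#'
#' Experiment 1: spread factor per set-size increment (overall and per
#' shadows condition) and the shadows-absent spread factor. Experiment 2:
#' population internal noise (degrees), integration exponent, and number of
#' integrated objects at set sizes 9 and 25. Experiment 3: threshold factor
#' for incongruent illumination, threshold factor per set-size increment,
#' and the lapse rate.
#'
#' @param fit an `en_fit`.
#' @return matrix of draws x derived quantities (named columns).
#' @export
derived_draws <- function(fit) {
  stopifnot(inherits(fit, "en_fit"))
  mu <- fit$mu
  if (fit$experiment == 1L) {
    cbind(spread_ratio_per_increment = exp(mu[, 3]),
          spread_ratio_shadows_present = exp(mu[, 3] - 0.5 * mu[, 5]),
          spread_ratio_shadows_absent = exp(mu[, 3] + 0.5 * mu[, 5]),
          shadow_absent_factor = exp(mu[, 2]))
  } else if (fit$experiment == 2L) {
    x <- 1.25 * stats::plogis(mu[, 2])
    cbind(sigma_int_pop = exp(mu[, 1]), exponent = x,
          n_at_9 = 9^x, n_at_25 = 25^x, midpoint_pop = mu[, 3])
  } else {
    out <- cbind(threshold_ratio_incongruent = exp(mu[, 2]),
                 threshold_ratio_per_increment = exp(mu[, 3]),
                 threshold_congruent = exp(mu[, 1] - 0.5 * mu[, 2]))
    if (!is.null(fit$shared)) {
      out <- cbind(out, lapse = 0.5 * stats::plogis(fit$shared[, 1]))
    }
    out
  }
}

#' @export
summary.en_fit <- function(object, level = 0.95, ...) {
  qs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  pop <- cbind(object$mu, object$s)
  colnames(pop) <- c(paste0("mu_", object$param_names),
                     paste0("s_", object$param_names))
  if (!is.null(object$shared)) pop <- cbind(pop, object$shared)
  der <- derived_draws(object)
  tab <- function(m) {
    q <- t(apply(m, 2, stats::quantile, probs = qs, names = FALSE))
    data.frame(parameter = colnames(m), lower = q[, 1], median = q[, 2],
               upper = q[, 3], row.names = NULL)
  }
  out <- list(experiment = object$experiment,
              population = tab(pop), derived = tab(der),
              diagnostics = object$diagnostics,
              converged = object$converged, level = level)
  class(out) <- "summary.en_fit"
  out
}

#' @export
print.summary.en_fit <- function(x, ...) {
  cat(sprintf("Hierarchical psychometric fit, experiment %d\n", x$experiment))
  cat(sprintf("Derived quantities (median and %d%% credible interval):\n",
              round(100 * x$level)))
  print(x$derived, digits = 3)
  if (isFALSE(x$converged)) {
    cat("NOTE: convergence diagnostics flagged; treat estimates with care.\n")
  }
  invisible(x)
}

#' @export
coef.en_fit <- function(object, ...) {
  est <- apply(object$mu, 2, stats::median)
  names(est) <- paste0("mu_", object$param_names)
  if (!is.null(object$shared)) {
    est <- c(est, apply(object$shared, 2, stats::median))
  }
  est
}

#' Posterior predictive response probabilities
#'
#' For every trial of `newlog` (default: the fitted log) and every
#' requested posterior draw, the model probability of the positive response
#' ("right" or "correct") given the trial's participant and stimulus.
#'
#' @param object an `en_fit`.
#' @param newlog optional trial log; participants must appear in the fit.
#' @param draw_ids draws to use (default: up to 100 equally spaced).
#' @param ... unused.
#' @return trials x draws matrix of probabilities.
#' @export
predict.en_fit <- function(object, newlog = NULL, draw_ids = NULL, ...) {
  log <- if (is.null(newlog)) object$log else newlog
  log <- log[log$experiment == object$experiment, , drop = FALSE]
  pidx <- match(log$participant, object$participants)
  if (anyNA(pidx)) {
    stop("participant(s) not in fit: ",
         paste(unique(log$participant[is.na(pidx)]), collapse = ", "))
  }
  nd <- dim(object$theta)[1]
  if (is.null(draw_ids)) {
    draw_ids <- unique(round(seq(1, nd, length.out = min(100, nd))))
  }
  out <- matrix(NA_real_, nrow(log), length(draw_ids))
  for (j in seq_along(draw_ids)) {
    d <- draw_ids[j]
    if (object$experiment == 1L) {
      bs <- object$theta[d, , 1:6, drop = FALSE][1, , ]
      bm <- object$theta[d, , 7:12, drop = FALSE][1, , ]
      if (is.null(dim(bs))) { bs <- matrix(bs, 1); bm <- matrix(bm, 1) }
      spread <- exp(tcrossprod(bs, object$X))   # P x 6
      mid <- tcrossprod(bm, object$X)
      ci <- match(log$condition, object$conditions$condition)
      out[, j] <- pf_cnorm(log$mean_angle,
                           mid[cbind(pidx, ci)], spread[cbind(pidx, ci)],
                           object$lapse)
    } else if (object$experiment == 2L) {
      si <- exp(object$theta[d, pidx, 1])
      x <- 1.25 * stats::plogis(object$theta[d, pidx, 2])
      mid <- object$theta[d, pidx, 3]
      spread <- en_spread(si, log$ext_noise_sd,
                          pmax(1, log$set_size^x))
      out[, j] <- pf_wrapped_cnorm(log$mean_angle, mid, spread, object$lapse)
    } else {
      bt <- object$theta[d, , 1:6, drop = FALSE][1, , ]
      if (is.null(dim(bt))) bt <- matrix(bt, 1)
      alpha <- exp(tcrossprod(bt, object$X))
      beta <- exp(object$theta[d, , 7])
      lam <- if (!is.null(object$shared))
        0.5 * stats::plogis(object$shared[d, 1]) else 0
      ci <- match(log$condition, object$conditions$condition)
      out[, j] <- pf_weibull(log$amplitude, alpha[cbind(pidx, ci)],
                             beta[pidx], 0.5, lam)
    }
  }
  out
}

#' Simulate response datasets from a fitted model
#'
#' Draws `nsim` replicate response vectors for the trials of `newlog`
#' (default: the fitted log), each generated from one posterior draw's
#' response probabilities - the generative side of the posterior
#' retrodictive machinery.
#'
#' @param object an `en_fit`.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param newlog optional trial log.
#' @param ... unused.
#' @return trials x `nsim` matrix of simulated positive-response
#'   indicators.
#' @export
simulate.en_fit <- function(object, nsim = 1, seed = NULL, newlog = NULL,
                            ...) {
  if (!is.null(seed)) set.seed(seed)
  nd <- dim(object$theta)[1]
  ids <- ((seq_len(nsim) - 1) %% nd) + 1
  ph <- predict(object, newlog, draw_ids = unique(ids))
  ph <- ph[, match(ids, unique(ids)), drop = FALSE]
  matrix(stats::rbinom(length(ph), 1, ph), nrow(ph))
}

#' @export
residuals.en_fit <- function(object, ...) {
  log <- object$log[object$log$experiment == object$experiment, ]
  y <- as.numeric(log$response %in% c("right", "correct"))
  y - rowMeans(predict(object))
}

#' Posterior retrodictive check
#'
#' Bins trials by stimulus level within each condition, overlays the
#' observed proportion of positive responses with posterior-predictive
#' intervals (responses re-simulated from the fitted model per draw), and
#' reports the fraction of bins whose observed proportion falls inside the
#' interval.
#'
#' @param fit an `en_fit`.
#' @param log optional trial log (default: the fitted log).
#' @param n_bins stimulus bins per condition (default 9).
#' @param n_draws posterior draws used for the predictive intervals.
#' @param level interval level (default 0.95).
#' @param seed seed for the predictive simulations.
#' @return an object of class `retro_check`: data.frame of bins plus a
#'   `coverage` attribute; `print()` and `plot()` methods.
#' @export
retrodictive_check <- function(fit, log = NULL, n_bins = 9, n_draws = 100,
                               level = 0.95, seed = 1) {
  stopifnot(inherits(fit, "en_fit"))
  if (is.null(log)) log <- fit$log
  log <- log[log$experiment == fit$experiment, , drop = FALSE]
  stim <- if (fit$experiment == 3L) log(log$amplitude) else log$mean_angle
  y <- as.numeric(log$response %in% c("right", "correct"))
  phat <- predict(fit, log, draw_ids = NULL)
  nd <- min(n_draws, ncol(phat))
  phat <- phat[, seq_len(nd), drop = FALSE]
  set.seed(.subseed(seed, 313))
  ysim <- matrix(stats::rbinom(length(phat), 1, phat), nrow(phat))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  res <- list()
  for (cc in sort(unique(log$condition))) {
    sel <- log$condition == cc
    br <- seq(min(stim[sel]), max(stim[sel]), length.out = n_bins + 1)
    bin <- cut(stim[sel], br, include.lowest = TRUE)
    counts <- tabulate(as.integer(bin), nbins = n_bins)
    empty <- counts == 0
    if (any(empty)) {
      warning(sum(empty), " empty stimulus bin(s) dropped in condition ", cc)
    }
    obs <- tapply(y[sel], bin, mean)
    sim_prop <- apply(ysim[sel, , drop = FALSE], 2,
                      function(z) tapply(z, bin, mean))
    lo <- apply(sim_prop, 1, stats::quantile, probs = qs[1], na.rm = TRUE)
    hi <- apply(sim_prop, 1, stats::quantile, probs = qs[2], na.rm = TRUE)
    mid <- (br[-1] + br[-length(br)]) / 2
    keep <- !empty
    res[[length(res) + 1]] <- data.frame(
      condition = cc, bin_mid = mid[keep], n = counts[keep],
      observed = as.numeric(obs[keep]), lower = lo[keep], upper = hi[keep],
      inside = as.numeric(obs[keep]) >= lo[keep] &
        as.numeric(obs[keep]) <= hi[keep])
  }
  out <- do.call(rbind, res)
  attr(out, "coverage") <- mean(out$inside)
  attr(out, "experiment") <- fit$experiment
  class(out) <- c("retro_check", "data.frame")
  out
}

#' @export
print.retro_check <- function(x, ...) {
  cat(sprintf(
    "<retro_check> %d bins, observed proportions inside the predictive interval: %.1f%%\n",
    nrow(x), 100 * attr(x, "coverage")))
  invisible(x)
}

#' @export
plot.retro_check <- function(x, ...) {
  xlab <- if (attr(x, "experiment") == 3L) "log amplitude" else
    "mean illumination angle (deg)"
  conds <- unique(x$condition)
  nc <- length(conds)
  oldpar <- graphics::par(mfrow = c(ceiling(nc / 3), min(nc, 3)),
                          mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  for (cc in conds) {
    s <- x[x$condition == cc, ]
    graphics::plot(s$bin_mid, s$observed, ylim = c(0, 1), pch = 19,
                   cex = 0.4 + sqrt(s$n) / 8, xlab = xlab,
                   ylab = "proportion positive",
                   main = paste("condition", cc), ...)
    graphics::arrows(s$bin_mid, s$lower, s$bin_mid, s$upper, angle = 90,
                     code = 3, length = 0.03, col = "grey50")
  }
  invisible(x)
}

#' @export
plot.en_fit <- function(x, ...) {
  plot(retrodictive_check(x), ...)
}

#' Prior-predictive draws of the condition-level psychometric parameter
#'
#' Draws the condition-level spread (experiments 1-2, degrees) or threshold
#' (experiment 3, amplitude fraction) implied by the population fixed-effect
#' priors, across all condition contrast patterns. Used to verify that the
#' priors keep nearly all mass inside the stimulus-resolvable range (see
#' [resolvable_range()]).
#'
#' @param experiment 1, 2 or 3.
#' @param n number of draws.
#' @return numeric vector of `n` prior-predictive parameter values.
#' @export
prior_predictive <- function(experiment, n = 1e4) {
  pr <- en_priors(experiment)
  if (experiment == 2L) {
    # the implied psychometric spread on external-noise trials - the trials
    # through which the equivalent-noise decomposition operates. (At zero
    # external noise the spread tends to sigma_int/sqrt(N), which the
    # design deliberately leaves unresolved at small values: those trials
    # saturate for any small internal noise.)
    si <- exp(stats::rnorm(n, pr$mu0[1], pr$sd0[1]))
    x <- 1.25 * stats::plogis(stats::rnorm(n, pr$mu0[2], pr$sd0[2]))
    lev <- sample(c(30, 48, 64, 80, 96, 112, 128), n, replace = TRUE)
    ss <- sample(c(9, 25), n, replace = TRUE)
    return(en_spread(si, lev, pmax(1, ss^x)))
  }
  cfg <- exp_config(experiment)
  X <- .design_matrix(cfg$conditions,
                      if (experiment == 1L) "shadows" else "congruent")
  beta <- matrix(stats::rnorm(n * 6, rep(pr$mu0[1:6], each = n),
                              rep(pr$sd0[1:6], each = n)), n, 6)
  lin <- beta %*% t(X)   # n x conditions
  exp(lin[cbind(seq_len(n), sample.int(nrow(X), n, replace = TRUE))])
}

#' Stimulus-resolvable parameter range of a design
#'
#' The range of psychometric spreads (or thresholds) that the design's
#' stimulus domain can distinguish: from half the smallest stimulus step
#' (below which the function is indistinguishable from a step) to the full
#' angular period of 360 degrees for the direction tasks, or four times the
#' largest amplitude for the shape task (beyond which the function is flat
#' over the domain).
#'
#' @param experiment 1, 2 or 3.
#' @return length-2 numeric vector (lower, upper).
#' @export
resolvable_range <- function(experiment) {
  cfg <- exp_config(experiment)
  if (experiment == 3L) {
    a <- cfg$stimulus_domain$amplitude
    c(min(a) / 2, 4 * max(a))
  } else {
    ang <- sort(unique(cfg$stimulus_domain$mean_angle))
    c(min(diff(ang)) / 2, 360)
  }
}
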