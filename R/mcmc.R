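# Adaptive Metropolis-within-Gibbs sampler for the package's hierarchical
# psychometric models. All models share one shape:
#   * each participant p has a K-vector theta_p of (transformed) parameters
#     with theta_pk ~ Normal(mu_k, s_k),
#   * population means mu_k carry Normal(mu0_k, sd0_k) priors and are
#     updated by conjugate Gibbs steps,
#   * population scales s_k carry half-Normal(scale0_k) priors and are
#     updated by random-walk Metropolis on log s,
#   * optional shared parameters (e.g. a common lapse) enter every
#     participant's likelihood and carry Normal priors on their own scale,
#   * participant parameters are updated one scalar at a time by
#     random-walk Metropolis with Robbins-Monro adaptation of the proposal
#     scales towards 0.44 acceptance during warmup.

.dhalfnorm_log <- function(x, scale) {
  ifelse(x <= 0, -Inf, log(2) + stats::dnorm(x, 0, scale, log = TRUE))
}

#' Hierarchical Metropolis-within-Gibbs sampler
#'
#' Generic engine behind [fit_exp1()], [fit_exp2()] and [fit_exp3()]. Not
#' usually called directly; exported for reuse and for calibration studies.
#'
#' @param data list of per-participant data objects.
#' @param loglik function(theta_p, shared, data_p) returning the
#'   log-likelihood of participant p's data.
#' @param K number of per-participant parameters.
#' @param mu0,sd0 Normal prior mean/SD for each population mean (length K).
#' @param re_scale0 half-Normal prior scale for each population SD
#'   (length K).
#' @param shared_init named numeric vector of shared-parameter initial
#'   values (NULL for none).
#' @param shared_prior_mean,shared_prior_sd Normal prior for each shared
#'   parameter.
#' @param n_warmup,n_save iterations for adaptation and for retained
#'   sampling per chain.
#' @param thin keep every `thin`-th post-warmup iteration.
#' @param chains number of chains (default 4).
#' @param seed integer seed.
#' @return list with `theta` (draws x participants x K array), `mu`, `s`,
#'   `shared` (draw matrices), `chain` (chain index per draw), `lp`
#'   (log-posterior per draw), and `accept` (mean acceptance rates).
#' @export
hier_mwg <- function(data, loglik, K, mu0, sd0, re_scale0,
                     shared_init = NULL, shared_prior_mean = NULL,
                     shared_prior_sd = NULL,
                     n_warmup = 800, n_save = 800, thin = 1, chains = 4,
                     seed = 1) {
  P <- length(data)
  stopifnot(length(mu0) == K, length(sd0) == K, length(re_scale0) == K)
  nsh <- length(shared_init)
  kept_per_chain <- floor(n_save / thin)
  n_total <- kept_per_chain * chains
  theta_out <- array(NA_real_, c(n_total, P, K))
  mu_out <- matrix(NA_real_, n_total, K)
  s_out <- matrix(NA_real_, n_total, K)
  sh_out <- if (nsh) matrix(NA_real_, n_total, nsh,
                            dimnames = list(NULL, names(shared_init))) else NULL
  lp_out <- numeric(n_total)
  chain_out <- integer(n_total)
  acc_all <- 0; prop_all <- 0
  out_row <- 0L
  for (ch in seq_len(chains)) {
    set.seed(.subseed(seed, 7000 + ch))
    mu <- mu0 + stats::rnorm(K, 0, 0.3 * pmin(sd0, 1))
    s <- re_scale0 * stats::runif(K, 0.4, 0.8)
    theta <- matrix(rep(mu, each = P), P, K) +
      matrix(stats::rnorm(P * K), P, K) * rep(s, each = P)
    shared <- if (nsh) shared_init + stats::rnorm(nsh, 0, 0.2) else numeric(0)
    ll <- vapply(seq_len(P), function(p) loglik(theta[p, ], shared,
                                                data[[p]]), numeric(1))
    if (any(!is.finite(ll))) {
      # fall back to prior means if a jittered start lands in a bad region
      theta <- matrix(rep(mu0, each = P), P, K)
      mu <- mu0
      shared <- if (nsh) shared_init else numeric(0)
      ll <- vapply(seq_len(P), function(p) loglik(theta[p, ], shared,
                                                  data[[p]]), numeric(1))
    }
    ls_theta <- matrix(log(0.2), P, K)   # log proposal scales
    ls_s <- rep(log(0.3), K)
    ls_sh <- rep(log(0.1), nsh)
    n_iter <- n_warmup + n_save
    for (it in seq_len(n_iter)) {
      adapt <- it <= n_warmup
      gain <- if (adapt) min(0.25, 3 / sqrt(it)) else 0
      # --- participant parameters ---
      for (p in seq_len(P)) {
        th <- theta[p, ]
        llp <- ll[p]
        for (k in seq_len(K)) {
          prop <- th
          prop[k] <- th[k] + exp(ls_theta[p, k]) * stats::rnorm(1)
          llnew <- loglik(prop, shared, data[[p]])
          logr <- llnew - llp +
            stats::dnorm(prop[k], mu[k], s[k], log = TRUE) -
            stats::dnorm(th[k], mu[k], s[k], log = TRUE)
          a <- if (is.finite(logr)) min(1, exp(logr)) else 0
          if (stats::runif(1) < a) {
            th <- prop; llp <- llnew
          }
          if (adapt) ls_theta[p, k] <- ls_theta[p, k] + gain * (a - 0.44)
          prop_all <- prop_all + 1; acc_all <- acc_all + a
        }
        theta[p, ] <- th
        ll[p] <- llp
      }
      # --- population means: conjugate Gibbs ---
      for (k in seq_len(K)) {
        prec <- 1 / sd0[k]^2 + P / s[k]^2
        m <- (mu0[k] / sd0[k]^2 + sum(theta[, k]) / s[k]^2) / prec
        mu[k] <- stats::rnorm(1, m, sqrt(1 / prec))
      }
      # --- population scales: RW on log s ---
      for (k in seq_len(K)) {
        s_new <- s[k] * exp(exp(ls_s[k]) * stats::rnorm(1))
        logr <- sum(stats::dnorm(theta[, k], mu[k], s_new, log = TRUE)) -
          sum(stats::dnorm(theta[, k], mu[k], s[k], log = TRUE)) +
          .dhalfnorm_log(s_new, re_scale0[k]) -
          .dhalfnorm_log(s[k], re_scale0[k]) +
          log(s_new) - log(s[k])
        a <- if (is.finite(logr)) min(1, exp(logr)) else 0
        if (stats::runif(1) < a) s[k] <- s_new
        if (adapt) ls_s[k] <- ls_s[k] + gain * (a - 0.44)
      }
      # --- shared parameters ---
      if (nsh) {
        for (j in seq_len(nsh)) {
          prop_sh <- shared
          prop_sh[j] <- shared[j] + exp(ls_sh[j]) * stats::rnorm(1)
          ll_new <- vapply(seq_len(P), function(p)
            loglik(theta[p, ], prop_sh, data[[p]]), numeric(1))
          logr <- sum(ll_new) - sum(ll) +
            stats::dnorm(prop_sh[j], shared_prior_mean[j],
                         shared_prior_sd[j], log = TRUE) -
            stats::dnorm(shared[j], shared_prior_mean[j],
                         shared_prior_sd[j], log = TRUE)
          a <- if (is.finite(logr)) min(1, exp(logr)) else 0
          if (stats::runif(1) < a) {
            shared <- prop_sh; ll <- ll_new
          }
          if (adapt) ls_sh[j] <- ls_sh[j] + gain * (a - 0.44)
        }
      }
      if (it > n_warmup && (it - n_warmup) %% thin == 0) {
        out_row <- out_row + 1L
        theta_out[out_row, , ] <- theta
        mu_out[out_row, ] <- mu
        s_out[out_row, ] <- s
        if (nsh) sh_out[out_row, ] <- shared
        lp_out[out_row] <- sum(ll) +
          sum(stats::dnorm(mu, mu0, sd0, log = TRUE)) +
          sum(.dhalfnorm_log(s, re_scale0)) +
          sum(stats::dnorm(as.vector(theta), rep(mu, each = P),
                           rep(s, each = P), log = TRUE))
        chain_out[out_row] <- ch
      }
    }
  }
  list(theta = theta_out, mu = mu_out, s = s_out, shared = sh_out,
       lp = lp_out, chain = chain_out,
       accept = acc_all / max(1, prop_all))
}

#' MCMC convergence diagnostics
#'
#' Split-free potential-scale-reduction (across chains, via
#' \pkg{coda}) and effective sample sizes for a set of monitored draws.
#'
#' @param draws matrix of draws (rows) x parameters (columns, named).
#' @param chain integer chain index per row.
#' @param rhat_max,ess_min thresholds beyond which the fit is flagged.
#' @return data.frame with `parameter`, `rhat`, `ess`, plus attribute
#'   `flagged` (logical).
#' @export
mcmc_diagnostics <- function(draws, chain, rhat_max = 1.01, ess_min = 400) {
  chains <- sort(unique(chain))
  keep <- which(apply(draws, 2, stats::sd) > 1e-12)
  ml <- coda::mcmc.list(lapply(chains, function(ch)
    coda::mcmc(draws[chain == ch, keep, drop = FALSE])))
  rh <- rep(NA_real_, ncol(draws))
  if (length(chains) > 1) {
    gd <- try(coda::gelman.diag(ml, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) rh[keep] <- gd$psrf[, 1]
  }
  ess <- rep(NA_real_, ncol(draws))
  ess[keep] <- as.numeric(coda::effectiveSize(ml))
  out <- data.frame(parameter = colnames(draws), rhat = rh, ess = ess)
  attr(out, "flagged") <- any(rh > rhat_max, na.rm = TRUE) ||
    any(ess < ess_min, na.rm = TRUE)
  out
}
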