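# Hierarchical fits: structure, priors, degenerate designs, and reduced
# recovery checks. Full-scale recovery lives in the acceptance tests.

test_that("prior-predictive parameters stay inside the resolvable range", {
  set.seed(71)
  for (e in 1:3) {
    draws <- prior_predictive(e, n = 1e5)
    rng <- resolvable_range(e)
    expect_gte(mean(draws >= rng[1] & draws <= rng[2]), 0.99)
  }
})

test_that("a null spread pattern yields a trend ratio near one", {
  logs <- do.call(rbind, lapply(1:4, function(i)
    make_exp1_log(paste0("p", i), spreads = rep(8, 6),
                  midpoints = rnorm(6, 0, 1), seed = 700 + i)))
  fit <- fit_exp1(logs, n_warmup = 300, n_save = 300, thin = 1,
                  chains = 2, seed = 2)
  der <- derived_draws(fit)
  ratio <- median(der[, "spread_ratio_per_increment"])
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
  expect_s3_class(fit, "en_fit")
  expect_named(summary(fit)$derived, c("parameter", "lower", "median",
                                       "upper"))
})

test_that("a single participant still returns a fit", {
  logs <- make_exp1_log("only", spreads = rep(10, 6), seed = 71)
  fit <- fit_exp1(logs, n_warmup = 150, n_save = 150, chains = 2, seed = 3)
  expect_s3_class(fit, "en_fit")
  expect_equal(length(fit$participants), 1)
  # population effects revert towards their priors: the shadow effect has
  # no information beyond one participant, so its posterior stays wide
  expect_gt(sd(fit$mu[, 2]), 0.1)
})

test_that("zero-integration observers give N near one at both set sizes", {
  logs <- do.call(rbind, lapply(1:4, function(i)
    make_en_log(paste0("p", i), sigma_int = 5, exponent = 0,
                n_per_cond = 250, seed = 720 + i)))
  fit <- fit_exp2(logs, n_warmup = 400, n_save = 400, thin = 1,
                  chains = 2, seed = 4)
  der <- derived_draws(fit)
  expect_lt(median(der[, "n_at_9"]), 1.25)
  expect_lt(median(der[, "n_at_25"]), 1.5)
})

test_that("an all-zero-external-noise log is flagged as degenerate", {
  logs <- make_en_log("p1", 5, 0.2, seed = 73)
  logs$ext_noise_sd <- 0
  logs2 <- logs; logs2$participant <- "p2"
  expect_warning(
    fit <- fit_exp2(rbind(logs, logs2), n_warmup = 50, n_save = 50,
                    chains = 2, seed = 5),
    "not jointly identifiable")
  expect_true(fit$degenerate)
  expect_false(fit$converged)
})

test_that("experiment-3 nulls recover: unit ratio and the true lapse", {
  set.seed(74)
  logs <- do.call(rbind, lapply(1:5, function(i)
    make_exp3_log(paste0("p", i), alphas = rep(0.06, 6), beta = 3,
                  lapse = 0.05, n_per_cond = 120, seed = 740 + i)))
  fit <- fit_exp3(logs, n_warmup = 400, n_save = 400, thin = 1,
                  chains = 2, seed = 6)
  der <- derived_draws(fit)
  q_ratio <- quantile(der[, "threshold_ratio_incongruent"], c(0.025, 0.975))
  expect_lt(q_ratio[1], 1); expect_gt(q_ratio[2], 1)
  q_lapse <- quantile(der[, "lapse"], c(0.025, 0.975))
  expect_lt(q_lapse[1], 0.05); expect_gt(q_lapse[2], 0.05)
})

test_that("retrodictive checks calibrate for a well-specified model and
           fail for shuffled responses", {
  logs <- do.call(rbind, lapply(1:3, function(i)
    make_exp1_log(paste0("p", i), spreads = rep(8, 6), seed = 750 + i)))
  fit <- fit_exp1(logs, n_warmup = 200, n_save = 200, chains = 2, seed = 7)
  rc <- retrodictive_check(fit, n_bins = 7, seed = 8)
  expect_gt(attr(rc, "coverage"), 0.8)
  # shuffling the responses destroys the stimulus-response link
  set.seed(76)
  shuffled <- fit$log
  shuffled$response <- sample(shuffled$response)
  rc2 <- retrodictive_check(fit, shuffled, n_bins = 7, seed = 9)
  expect_lt(attr(rc2, "coverage"), attr(rc, "coverage"))
  expect_lt(attr(rc2, "coverage"), 0.6)
})

test_that("pointwise EN estimates track the generating parameters", {
  logs <- do.call(rbind, lapply(1:3, function(i)
    make_en_log(paste0("p", i), sigma_int = 5, exponent = 0.1845,
                seed = 760 + i)))
  fit <- fit_en_pointwise(logs)
  si <- sigma_int_estimates(fit)
  expect_equal(unname(si), rep(5, 3), tolerance = 0.35)
  ph <- predict(fit, logs)
  expect_equal(ncol(ph), 1)
  expect_true(all(ph > 0 & ph < 1))
})

test_that("rank statistics of truths under their posteriors are uniform", {
  # reduced simulation-based calibration on the equivalent-noise model:
  # draw truths from the population model, simulate small datasets, fit
  # with reduced draws, and check the rank of the truth in its posterior
  n_rep <- 24
  ranks <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(7700 + r)
    mu_lsi <- rnorm(1, log(6), 0.5)
    logs <- do.call(rbind, lapply(1:2, function(i)
      make_en_log(paste0("p", i), sigma_int = exp(rnorm(1, mu_lsi, 0.3)),
                  exponent = 0.2, n_per_cond = 60, seed = 7800 + 10 * r + i)))
    fit <- suppressWarnings(
      fit_exp2(logs, n_warmup = 150, n_save = 150, thin = 3, chains = 1,
               seed = 7900 + r))
    ranks[r] <- mean(fit$mu[, 1] < mu_lsi)
  }
  # chi-square uniformity test over 4 bins at alpha = 0.01
  counts <- tabulate(cut(ranks, seq(0, 1, 0.25), include.lowest = TRUE,
                         labels = FALSE), nbins = 4)
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})
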