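# Residual object-reliance attribution: residual definition, the sign
# reversal, reference bands, and attribution specificity.

# minimal en_residuals object with known residuals and azimuths
fake_residuals <- function(res, az, phat = NULL) {
  n <- nrow(az)
  log <- data.frame(
    participant = "p1", experiment = 2L, run = NA, trial = seq_len(n),
    condition = 1L, set_size = ncol(az), shadows = NA, congruent = NA,
    mean_angle = 0, ext_noise_sd = 64, amplitude = NA,
    per_object_azimuths = vapply(seq_len(n), function(i)
      as.character(jsonlite::toJSON(az[i, ], digits = NA)), character(1)),
    response = "right", correct = NA, is_catch = FALSE)
  structure(list(log = log, res = matrix(res, ncol = 1),
                 phat = if (is.null(phat)) matrix(0.5, n, 1) else phat),
            class = "en_residuals")
}

test_that("residuals are the observed indicator minus the model probability", {
  set.seed(81)
  logs <- make_en_log("p1", 5, 0.2, n_per_cond = 120, seed = 810)
  fit <- fit_en_pointwise(logs)
  resid <- compute_residuals(fit)
  # restricted to external-noise trials only
  expect_true(all(resid$log$ext_noise_sd > 0))
  expect_true(all(!resid$log$is_catch))
  # definition check against an independently computed probability
  th <- fit$theta[1, 1, ]
  p_oracle <- pf_wrapped_cnorm(
    resid$log$mean_angle, th[3],
    en_spread(exp(th[1]), resid$log$ext_noise_sd,
              pmax(1, resid$log$set_size^(1.25 * plogis(th[2])))), 0.01)
  y <- as.numeric(resid$log$response == "right")
  expect_equal(resid$res[, 1], y - p_oracle, tolerance = 1e-12)
  expect_equal(resid$res[y == 1, 1], 1 - p_oracle[y == 1])
  expect_equal(resid$res[y == 0, 1], -p_oracle[y == 0])
})

test_that("participants missing from the fit are rejected", {
  logs <- make_en_log("p1", 5, 0.2, n_per_cond = 60, seed = 811)
  fit <- fit_en_pointwise(logs)
  other <- logs; other$participant <- "stranger"
  expect_error(compute_residuals(fit, other), "absent")
})

test_that("residual signs are reversed where the object angle is negative", {
  az <- matrix(c(rep(-40, 50), rep(40, 50)), ncol = 1)
  r <- fake_residuals(rep(0.3, 100), az)
  expect_warning(s <- object_summary(r), "empty angle bin")
  # negative-angle trials contribute -0.3, positive +0.3; bin-averaged the
  # two halves cancel
  expect_equal(s$score, 0, tolerance = 1e-12)
  az2 <- matrix(rep(-40, 100), ncol = 1)
  expect_warning(s2 <- object_summary(fake_residuals(rep(0.3, 100), az2)),
                 "empty angle bin")
  expect_equal(s2$score, -0.3, tolerance = 1e-12)
})

test_that("a model-consistent integrator stays inside the reference band", {
  set.seed(82)
  logs <- do.call(rbind, lapply(1:4, function(i) {
    l <- simulate_random_design(observer(5, exponent = 0.5, lapse = 0.01),
                                330, 9, seed = 820 + i,
                                participant = paste0("p", i))
    l
  }))
  fit <- fit_en_pointwise(logs)
  resid <- compute_residuals(fit)
  expect_equal(mean(resid$res), 0, tolerance = 0.02)
  s <- object_summary(resid)
  b <- reference_band(resid, n_replicates = 300, seed = 83)
  flags <- reliance_flags(s, b)
  expect_false(any(flags$above_band))
  # the band brackets zero
  expect_true(all(b$lower < 0 & b$upper > 0))
})

test_that("reference bands are deterministic under seed and shrink with n", {
  set.seed(84)
  obs <- observer(5, exponent = 0.3, lapse = 0.01)
  small <- simulate_random_design(obs, 330, 9, seed = 85)
  big <- simulate_random_design(obs, 3300, 9, seed = 86)
  fit_s <- fit_en_pointwise(small)
  fit_b <- fit_en_pointwise(big)
  rs <- compute_residuals(fit_s)
  rb <- compute_residuals(fit_b)
  b1 <- reference_band(rs, n_replicates = 200, seed = 87)
  b2 <- reference_band(rs, n_replicates = 200, seed = 87)
  expect_identical(b1, b2)
  b3 <- reference_band(rb, n_replicates = 200, seed = 87)
  w_small <- mean(b1$upper - b1$lower)
  w_big <- mean(b3$upper - b3$lower)
  # Monte-Carlo scaling: width ratio near sqrt(10)
  expect_gt(w_small / w_big, 2.2)
  expect_lt(w_small / w_big, 4.5)
})

test_that("attribution is specific to the attended object", {
  set.seed(88)
  w <- c(0.8, rep(0.2 / 8, 8))
  logs <- do.call(rbind, lapply(1:6, function(i)
    simulate_random_design(observer(5, weights = w, lapse = 0.01), 330, 9,
                           seed = 880 + i, participant = paste0("p", i))))
  fit <- fit_en_pointwise(logs)
  resid <- compute_residuals(fit)
  s <- object_summary(resid)
  expect_equal(which.max(s$score), 1)
  b <- reference_band(resid, n_replicates = 300, seed = 89)
  flags <- reliance_flags(s, b)
  expect_true(flags$above_band[flags$object == 1])
})
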