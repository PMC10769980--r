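# Generative observers: limiting behaviour, equivalent-noise consistency,
# attention weights, and the shape-task response model.

test_that("a near-noiseless full integrator always responds with the mean", {
  obs <- observer(sigma_int = 1e-3, n_integrated = 9)
  tr <- sim_direction_trials(obs, rep(50, 200), 0, 9)
  expect_true(all(tr$response == "right"))
  tr2 <- sim_direction_trials(obs, rep(-50, 200), 0, 9)
  expect_true(all(tr2$response == "left"))
})

test_that("a fully lapsing observer guesses at chance", {
  set.seed(51)
  obs <- observer(sigma_int = 1e-3, n_integrated = 1, lapse = 1)
  tr <- sim_direction_trials(obs, rep(80, 4000), 0, 9)
  expect_equal(mean(tr$response == "right"), 0.5, tolerance = 0.03)
})

test_that("integrating more objects than the scene holds errors", {
  obs <- observer(5, n_integrated = 10)
  expect_error(sim_direction_trials(obs, 0, 0, 9), "exceeds")
})

test_that("the sampling observer's response curve follows the EN law", {
  set.seed(52)
  obs <- observer(sigma_int = 5, n_integrated = 3)
  angles <- seq(-70, 70, by = 20)
  n_per <- 4000
  spread <- en_spread(5, 48, 3)
  for (a in angles) {
    tr <- sim_direction_trials(obs, rep(a, n_per), 48, 9)
    p_model <- pf_wrapped_cnorm(a, 0, spread)
    expect_lt(abs(mean(tr$response == "right") - p_model), 0.025)
  }
})

test_that("weighted observers ignore objects with zero weight", {
  set.seed(53)
  obs <- observer(sigma_int = 5, weights = c(1, rep(0, 8)))
  n <- 6000
  tr <- sim_direction_trials(obs, rep(0, n), 96, 9)
  y <- as.numeric(tr$response == "right")
  az <- tr$azimuths
  fit <- glm(y ~ az, family = binomial())
  z <- summary(fit)$coefficients[-1, "z value"]
  expect_gt(abs(z[1]), 10)       # attended object drives the response
  expect_true(all(abs(z[-1]) < 4))  # unattended objects do not
})

test_that("fitted spread increases monotonically with internal noise", {
  set.seed(54)
  spreads <- vapply(c(3, 5, 10, 20), function(si) {
    obs <- observer(si, n_integrated = 9)
    a <- runif(3000, -60, 60)
    tr <- sim_direction_trials(obs, a, 0, 9)
    g <- suppressWarnings(
      glm((tr$response == "right") ~ a, family = binomial("probit")))
    1 / coef(g)[2]
  }, numeric(1))
  expect_true(all(diff(spreads) > 0))
  # and matches sigma_int / sqrt(N) for the full integrator
  expect_equal(unname(spreads[2]), 5 / 3, tolerance = 0.25)
})

test_that("non-lapsing observers ace the catch trials", {
  set.seed(55)
  for (si in c(5, 10)) {
    obs <- observer(si, n_integrated = 1)
    tr <- sim_direction_trials(obs, rep(c(-90, 90), 1000), 0, 9)
    acc <- mean((tr$response == "right") == (rep(c(-90, 90), 1000) > 0))
    expect_gt(acc, 0.99)
  }
})

test_that("shape responses follow the Weibull truth", {
  set.seed(56)
  r0 <- simulate_shape_response(rep(0, 4000), 0.06, 3)
  expect_equal(mean(r0 == "correct"), 0.5, tolerance = 0.03)
  r1 <- simulate_shape_response(rep(0.06, 10000), 0.06, 3)
  expect_equal(mean(r1 == "correct"), 0.816, tolerance = 0.015)
  r2 <- simulate_shape_response(rep(0.2, 2000), 0.06, 8)
  expect_gt(mean(r2 == "correct"), 0.995)
})

test_that("scene-level responses agree with the trial simulator", {
  set.seed(57)
  sc <- scene_spec(9, 50, 0)
  obs <- observer(1e-3, n_integrated = 9)
  expect_equal(simulate_direction_response(sc, obs), "right")
})

test_that("observer constructor enforces exactly one integration mode", {
  expect_error(observer(5), "exactly one")
  expect_error(observer(5, n_integrated = 2, exponent = 0.5), "exactly one")
  expect_error(observer(-1, n_integrated = 2), "sigma_int")
  expect_error(observer(5, weights = c(-1, 2)), "non-negative")
  expect_error(observer(5, exponent = 2), "1.25")
})
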