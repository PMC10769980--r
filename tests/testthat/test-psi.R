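# Psi-marginal staircase: Bayes updating against brute-force oracles,
# expected-entropy selection, the sign-flip rule, and posterior consistency.

# small spread x midpoint lattice over a handful of angles
tiny_lattice <- function(n_spread = 15, n_mid = 15, angles = c(-48, -32,
                         -16, -2, 14, 30, 46), tau = 0.05) {
  psi_lattice(
    grids = list(spread = exp(seq(log(2), log(40), length.out = n_spread)),
                 midpoint = seq(-14, 14, length.out = n_mid)),
    interest = "spread",
    stimulus_domain = data.frame(mean_angle = angles),
    likelihood_fn = function(stim, nodes)
      pf_cnorm(stim$mean_angle, nodes$midpoint, nodes$spread, 0.01),
    tau = tau)
}

test_that("posterior update reduces to two-point Bayes by hand", {
  lat <- psi_lattice(
    grids = list(g = c(1, 2)), interest = "g",
    stimulus_domain = data.frame(s = 0),
    likelihood_fn = function(stim, nodes) ifelse(nodes$g == 1, 0.8, 0.2),
    response_labels = c("left", "right"))
  up <- psi_update(lat, data.frame(s = 0), "right")
  expect_equal(up$posterior, c(0.8, 0.2))
  dn <- psi_update(lat, data.frame(s = 0), "left")
  expect_equal(dn$posterior, c(0.2, 0.8))
  expect_error(psi_update(lat, data.frame(s = 0), "maybe"), "response")
})

test_that("a constant likelihood leaves the posterior at the prior", {
  lat <- psi_lattice(
    grids = list(g = 1:4), interest = "g",
    stimulus_domain = data.frame(s = 1),
    likelihood_fn = function(stim, nodes) rep(0.5, nrow(nodes)))
  up <- psi_update(lat, data.frame(s = 1), "right")
  expect_equal(up$posterior, lat$prior)
  # and every stimulus is then exactly as uninformative as doing nothing
  marg_H <- -sum(lat$posterior * log2(lat$posterior))
  expect_equal(psi_expected_entropy(lat), rep(marg_H, 1), tolerance = 1e-12)
})

test_that("20 random trials match a brute-force product-of-likelihoods", {
  set.seed(31)
  lat <- tiny_lattice()
  nodes <- lat$nodes
  prior <- lat$prior
  brute <- prior
  for (t in 1:20) {
    s <- sample.int(nrow(lat$stimulus_domain), 1)
    stim <- lat$stimulus_domain[s, , drop = FALSE]
    resp <- sample(c("left", "right"), 1)
    lat <- psi_update(lat, stim, resp)
    p_pos <- pf_cnorm(stim$mean_angle, nodes$midpoint, nodes$spread, 0.01)
    brute <- brute * (if (resp == "right") p_pos else 1 - p_pos)
  }
  brute <- brute / sum(brute)
  expect_equal(lat$posterior, brute, tolerance = 1e-12)
  expect_equal(sum(lat$posterior), 1, tolerance = 1e-12)
  expect_equal(nrow(psi_history(lat)), 20)
})

test_that("the posterior is invariant to the order of a fixed trial set", {
  set.seed(32)
  lat0 <- tiny_lattice()
  trials <- data.frame(
    s = sample.int(7, 15, replace = TRUE),
    r = sample(c("left", "right"), 15, replace = TRUE))
  run <- function(ord) {
    lat <- lat0
    for (i in ord) {
      lat <- psi_update(lat, lat0$stimulus_domain[trials$s[i], , drop = FALSE],
                        trials$r[i])
    }
    lat$posterior
  }
  expect_equal(run(1:15), run(sample(1:15)), tolerance = 1e-12)
})

test_that("expected entropy matches a two-outcome hand enumeration", {
  # single interest dimension with 2 nodes and one stimulus
  p_nodes <- c(0.9, 0.3)
  lat <- psi_lattice(
    grids = list(g = c(1, 2)), interest = "g",
    stimulus_domain = data.frame(s = 0),
    likelihood_fn = function(stim, nodes) p_nodes)
  H <- function(w) { w <- w / sum(w); -sum(ifelse(w > 0, w * log2(w), 0)) }
  q1 <- mean(p_nodes)             # uniform prior
  hand <- q1 * H(0.5 * p_nodes) + (1 - q1) * H(0.5 * (1 - p_nodes))
  expect_equal(psi_expected_entropy(lat), hand, tolerance = 1e-12)
})

test_that("a point-mass posterior has zero expected entropy everywhere", {
  lat <- tiny_lattice()
  lat$posterior <- rep(0, nrow(lat$nodes))
  lat$posterior[100] <- 1
  expect_equal(psi_expected_entropy(lat), rep(0, 7), tolerance = 1e-12)
  est <- psi_estimates(lat)
  expect_equal(est$mean, lat$nodes$spread[100], tolerance = 1e-12)
  expect_equal(est$median, lat$nodes$spread[100])
})

test_that("stimulus selection matches exhaustive entropy search at tau = 0", {
  set.seed(33)
  lat <- tiny_lattice(tau = 0)
  for (t in 1:8) {
    stim <- psi_select(lat, flip_run_length = Inf)
    eh <- psi_expected_entropy(lat)
    expect_equal(stim$mean_angle,
                 lat$stimulus_domain$mean_angle[which.min(eh)])
    lat <- psi_update(lat, stim, sample(c("left", "right"), 1))
  }
})

test_that("the sign-flip rule breaks runs of same-sign mean angles", {
  # make +40 uniquely informative and -40 useless, so selection would
  # otherwise always return +40
  lat <- psi_lattice(
    grids = list(g = c(1, 2)), interest = "g",
    stimulus_domain = data.frame(mean_angle = c(-40, 40)),
    likelihood_fn = function(stim, nodes) {
      if (stim$mean_angle > 0) c(0.9, 0.1) else c(0.5, 0.5)
    }, tau = 0)
  set.seed(34)
  for (i in 1:5) lat <- psi_update(lat, data.frame(mean_angle = 40), "right")
  sel <- psi_select(lat)
  expect_equal(sel$mean_angle, -40)
  # without a same-sign run the argmin is returned untouched
  lat2 <- psi_update(psi_reset(lat), data.frame(mean_angle = -40), "left")
  expect_equal(psi_select(lat2)$mean_angle, 40)
})

test_that("selection from an empty domain errors", {
  lat <- tiny_lattice()
  lat$stimulus_domain <- lat$stimulus_domain[0, , drop = FALSE]
  expect_error(psi_select(lat), "empty")
})

test_that("marginal estimates match a direct-summation oracle", {
  set.seed(35)
  lat <- tiny_lattice()
  w <- runif(nrow(lat$nodes)); w <- w / sum(w)
  lat$posterior <- w
  est <- psi_estimates(lat)
  marg <- tapply(w, lat$nodes$spread, sum)
  vals <- as.numeric(names(marg))
  expect_equal(est$mean, sum(vals * marg), tolerance = 1e-12)
  expect_equal(est$median, vals[which(cumsum(marg) >= 0.5)[1]])
})

test_that("staircase state survives a JSON round trip", {
  set.seed(36)
  lat <- tiny_lattice()
  for (i in 1:6) {
    lat <- psi_update(lat, psi_select(lat), sample(c("left", "right"), 1))
  }
  j <- psi_to_json(lat)
  lat2 <- psi_from_json(j, function(stim, nodes)
    pf_cnorm(stim$mean_angle, nodes$midpoint, nodes$spread, 0.01))
  expect_equal(lat2$posterior, lat$posterior, tolerance = 1e-12)
  expect_equal(psi_history(lat2), psi_history(lat))
})

test_that("330 trials concentrate the posterior around on-grid truth", {
  cfg <- exp_config(1)
  lat0 <- make_psi_lattice(cfg, 1)
  sp_grid <- cfg$grids$spread
  mid_grid <- cfg$grids$midpoint
  true_sp <- sp_grid[16]
  true_mid <- mid_grid[11]
  # 3x3 neighbourhood of the truth in (spread, midpoint)
  near <- abs(match(round(lat0$nodes$spread, 10),
                    round(sp_grid, 10)) - 16) <= 1 &
    abs(match(round(lat0$nodes$midpoint, 10),
              round(mid_grid, 10)) - 11) <= 1
  masses <- vapply(1:20, function(rep) {
    set.seed(4000 + rep)
    lat <- psi_reset(lat0)
    for (t in 1:330) {
      stim <- psi_select(lat)
      p <- pf_cnorm(stim$mean_angle, true_mid, true_sp, 0.01)
      resp <- if (runif(1) < p) "right" else "left"
      lat <- psi_update(lat, stim, resp)
    }
    sum(lat$posterior[near])
  }, numeric(1))
  # typical sessions concentrate >= 90% of the mass at the truth; no
  # session may drift away from it (mass split across adjacent log-spaced
  # nodes is a resolution effect, not an updating failure)
  expect_gte(median(masses), 0.9)
  expect_gt(min(masses), 1 / 3)
})
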