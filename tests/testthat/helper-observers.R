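# Shared fixture builders: quick response-level trial logs that skip the
# adaptive staircase (stimuli drawn uniformly from the design's domain),
# used where tests need data volume rather than staircase behaviour.

make_en_log <- function(pid, sigma_int, exponent, midpoint = 0,
                        n_per_cond = 330, lapse = 0.01, seed = 1) {
  dom <- exp_config(2)$stimulus_domain
  set.seed(seed)
  out <- lapply(c(9, 25), function(ss) {
    pick <- sample.int(nrow(dom), n_per_cond, replace = TRUE)
    obs <- observer(sigma_int, exponent = exponent, bias = midpoint,
                    lapse = lapse)
    tr <- sim_direction_trials(obs, dom$mean_angle[pick],
                               dom$ext_noise_sd[pick], ss)
    data.frame(participant = pid, experiment = 2L, run = NA_integer_,
               trial = seq_len(n_per_cond),
               condition = match(ss, c(9, 25)), set_size = ss,
               shadows = NA, congruent = NA,
               mean_angle = dom$mean_angle[pick],
               ext_noise_sd = dom$ext_noise_sd[pick],
               amplitude = NA_real_, per_object_azimuths = "",
               response = tr$response, correct = NA, is_catch = FALSE)
  })
  do.call(rbind, out)
}

make_exp1_log <- function(pid, spreads, midpoints = rep(0, 6),
                          n_per_cond = 110, lapse = 0.01, seed = 1) {
  cfg <- exp_config(1)
  ang <- cfg$stimulus_domain$mean_angle
  set.seed(seed)
  out <- lapply(1:6, function(cc) {
    a <- sample(ang, n_per_cond, replace = TRUE)
    p <- pf_cnorm(a, midpoints[cc], spreads[cc], lapse)
    resp <- ifelse(runif(n_per_cond) < p, "right", "left")
    data.frame(participant = pid, experiment = 1L, run = NA_integer_,
               trial = seq_len(n_per_cond), condition = cc,
               set_size = cfg$conditions$set_size[cc],
               shadows = cfg$conditions$shadows[cc], congruent = NA,
               mean_angle = a, ext_noise_sd = 0, amplitude = NA_real_,
               per_object_azimuths = "", response = resp,
               correct = (resp == "right") == (a > 0), is_catch = FALSE)
  })
  do.call(rbind, out)
}

make_exp3_log <- function(pid, alphas, beta = 3, lapse = 0.02,
                          n_per_cond = 56, seed = 1) {
  cfg <- exp_config(3)
  amp <- cfg$stimulus_domain$amplitude
  set.seed(seed)
  out <- lapply(1:6, function(cc) {
    a <- sample(amp, n_per_cond, replace = TRUE)
    resp <- simulate_shape_response(a, alphas[cc], beta, 0.5, lapse)
    data.frame(participant = pid, experiment = 3L, run = NA_integer_,
               trial = seq_len(n_per_cond), condition = cc,
               set_size = cfg$conditions$set_size[cc], shadows = NA,
               congruent = cfg$conditions$congruent[cc],
               mean_angle = NA_real_, ext_noise_sd = NA_real_,
               amplitude = a, per_object_azimuths = "",
               response = resp, correct = resp == "correct",
               is_catch = FALSE)
  })
  do.call(rbind, out)
}

# condition-level truths used across recovery tests: spread grows by a
# factor per set-size increment and by a shadows-absent factor
exp1_truth_spreads <- function(base = 8, ratio = 1.2, shadow_factor = 3.36) {
  cond <- exp_config(1)$conditions
  rank <- match(cond$set_size, c(1, 9, 25)) - 2
  base * ratio^rank * ifelse(cond$shadows, 1, shadow_factor)
}
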