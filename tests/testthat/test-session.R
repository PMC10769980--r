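# Session plans, staircase-driven simulation, trial-log IO, exclusions.

test_that("session plans reproduce the specified trial counts", {
  set.seed(61)
  p1 <- build_session_plan(exp_config(1))
  expect_equal(nrow(p1), 660)
  expect_equal(as.integer(table(p1$condition)), rep(110L, 6))
  expect_equal(sum(p1$is_catch), 60)
  expect_equal(as.integer(table(p1$run)), rep(66L, 10))
  expect_true(all(abs(p1$catch_mean_angle[p1$is_catch]) == 70.25))

  p2 <- build_session_plan(exp_config(2))
  expect_equal(nrow(p2), 660)
  expect_equal(as.integer(table(p2$condition)), rep(330L, 2))
  expect_equal(sum(p2$is_catch), 60)
  expect_true(all(abs(p2$catch_mean_angle[p2$is_catch]) == 90))

  p3 <- build_session_plan(exp_config(3))
  expect_equal(nrow(p3), 336)
  expect_equal(as.integer(table(p3$condition)), rep(56L, 6))
  expect_equal(as.integer(table(p3$run)), rep(42L, 8))
  expect_true(all(p3$catch_amplitude[p3$is_catch] == 0.2))
})

test_that("condition counts are invariant to the interleaving seed", {
  set.seed(1); a <- build_session_plan(exp_config(3))
  set.seed(2); b <- build_session_plan(exp_config(3))
  expect_equal(table(a$condition, a$is_catch), table(b$condition, b$is_catch))
  expect_false(identical(a$condition, b$condition))
})

test_that("trial counts that do not divide into runs are rejected", {
  cfg <- exp_config(1)
  cfg$n_catch <- 11L
  expect_error(build_session_plan(cfg), "runs")
})

test_that("simulated sessions are fully deterministic under seed", {
  cfg <- exp_config(3)
  po <- pf_observer(data.frame(condition = 1:6, alpha = 0.06, beta = 3,
                               lapse = 0.02))
  a <- simulate_session(cfg, po, seed = 77)
  b <- simulate_session(cfg, po, seed = 77)
  attr(a, "lattices") <- attr(b, "lattices") <- NULL
  attr(a, "psi_estimates") <- attr(b, "psi_estimates") <- NULL
  expect_identical(a, b)
  c2 <- simulate_session(cfg, po, seed = 78)
  expect_false(identical(a$amplitude, c2$amplitude))
})

test_that("catch trials bypass the staircase", {
  cfg <- exp_config(3)
  po <- pf_observer(data.frame(condition = 1:6, alpha = 0.06, beta = 3,
                               lapse = 0.02))
  log <- simulate_session(cfg, po, seed = 79)
  lats <- attr(log, "lattices")
  expect_equal(vapply(lats, function(l) l$n_hist, integer(1)), rep(52L, 6))
  expect_equal(sum(log$is_catch), 24)
  expect_true(all(log$amplitude[log$is_catch] == 0.2))
})

test_that("trial logs round-trip losslessly through CSV", {
  set.seed(62)
  obs <- observer(5, n_integrated = 2)
  log <- simulate_random_design(obs, 50, 9, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_trial_log(log, f)
  back <- read_trial_log(f)
  expect_equal(back$response, log$response)
  expect_equal(back$mean_angle, log$mean_angle)
  expect_equal(azimuth_matrix(back), azimuth_matrix(log))
})

test_that("schema violations are reported with column and row", {
  set.seed(63)
  log <- simulate_random_design(observer(5, n_integrated = 1), 10, 9,
                                seed = 4)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(log[, setdiff(names(log), "response")], f,
                   row.names = FALSE)
  expect_error(read_trial_log(f), "response")
  log2 <- log
  log2$per_object_azimuths[3] <- "[1, 2]"
  f2 <- tempfile(fileext = ".csv")
  write_trial_log(log2, f2)
  expect_error(read_trial_log(f2), "row 3")
})

# build a catch-trial log with an exact accuracy for one participant
catch_log <- function(pid, n_correct, n_total) {
  data.frame(participant = pid, experiment = 2L, run = 1L,
             trial = seq_len(n_total), condition = 1L, set_size = 9L,
             shadows = NA, congruent = NA,
             mean_angle = 90, ext_noise_sd = 0, amplitude = NA_real_,
             per_object_azimuths = "", response = "right",
             correct = rep(c(TRUE, FALSE),
                           c(n_correct, n_total - n_correct)),
             is_catch = TRUE)
}

test_that("exclusion screens apply the reference boundary rules exactly", {
  log <- rbind(catch_log("below", 899, 1000),
               catch_log("at", 900, 1000),
               catch_log("clean", 1000, 1000))
  si <- c(below = 5, at = 5, clean = 26)
  res <- apply_exclusions(log, sigma_int = si)
  expect_setequal(res$included, "at")
  rep_ <- res$report
  expect_true(rep_$excluded[rep_$participant == "below"])   # 89.9% < 90%
  expect_false("at" %in% rep_$participant[rep_$excluded &
                 grepl("catch", rep_$reason)])              # exactly 90% kept
  expect_match(rep_$reason[rep_$participant == "clean"], "internal noise")
  # 24 and 25 degrees pass the internal-noise screen, 26 does not
  si2 <- c(below = 24, at = 25, clean = 26)
  res2 <- apply_exclusions(rbind(catch_log("at", 1000, 1000),
                                 catch_log("clean", 1000, 1000)),
                           sigma_int = si2)
  expect_setequal(res2$included, "at")
})

test_that("exclusions are idempotent and order-independent", {
  log <- rbind(catch_log("a", 899, 1000), catch_log("b", 950, 1000))
  r1 <- apply_exclusions(log)
  r2 <- apply_exclusions(log[rev(seq_len(nrow(log))), ])
  expect_setequal(r1$included, r2$included)
  sub <- log[log$participant %in% r1$included, ]
  expect_setequal(apply_exclusions(sub)$included, r1$included)
})

test_that("participants with no catch trials raise an error", {
  log <- catch_log("a", 10, 10)
  log$is_catch <- FALSE
  expect_error(apply_exclusions(log), "no catch")
})
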