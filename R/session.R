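# Experiment orchestration: the three reference designs, session plans,
# staircase-driven simulation, trial-log CSV IO, and the exclusion screens.

#' Configuration of one of the three reference experiment designs
#'
#' Encodes the trial counts, conditions, catch levels, stimulus domains and
#' staircase lattices of the three designs:
#' * Experiment 1 - left/right judgement, set size (1/9/25) x cast shadows,
#'   100 staircase + 10 catch trials per condition (660 total, 10 runs of
#'   66); angles -70.25..+70.25 in 0.5 deg steps; catch at +/-70.25 deg.
#' * Experiment 2 - left/right judgement under external noise, set sizes 9
#'   and 25, 300 staircase + 30 catch per condition (660 total, 10 runs of
#'   66); mean angle crossed with noise levels {0,30,48,64,80,96,112,128};
#'   catch at +/-90 deg with zero noise.
#' * Experiment 3 - 2AFC shape identification, set size x illumination
#'   congruence, 52 staircase + 4 catch per condition (336 total, 8 runs of
#'   42); foil amplitudes 0.01..0.2; catch at amplitude 0.2.
#'
#' @param experiment 1, 2 or 3.
#' @param mean_angle_step Experiment-2 staircase angle step in degrees
#'   (default 5; the reference design leaves the step open).
#' @param n_amplitudes Experiment-3 staircase amplitude-grid size
#'   (default 41 log-spaced values).
#' @param lapse fixed lapse rate assumed by the staircase response model
#'   (default 0.01).
#' @param tau "similarly informative" tolerance passed to [psi_lattice()].
#' @return an object of class `exp_config`.
#' @export
exp_config <- function(experiment, mean_angle_step = 5, n_amplitudes = 41,
                       lapse = 0.01, tau = 0.05) {
  experiment <- as.integer(experiment)
  cfg <- switch(as.character(experiment),
    "1" = list(
      conditions = data.frame(condition = 1:6,
                              set_size = rep(c(1L, 9L, 25L), 2),
                              shadows = rep(c(TRUE, FALSE), each = 3)),
      n_staircase = 100L, n_catch = 10L,
      catch = data.frame(mean_angle = 70.25, ext_noise_sd = 0),
      run_length = 66L, n_runs = 10L,
      stimulus_domain = data.frame(mean_angle = seq(-70.25, 70.25, by = 0.5)),
      grids = list(spread = exp(seq(log(1), log(64), length.out = 31)),
                   midpoint = seq(-20, 20, length.out = 21)),
      interest = "spread",
      response_labels = c("left", "right")),
    "2" = list(
      conditions = data.frame(condition = 1:2, set_size = c(9L, 25L)),
      n_staircase = 300L, n_catch = 30L,
      catch = data.frame(mean_angle = 90, ext_noise_sd = 0),
      run_length = 66L, n_runs = 10L,
      stimulus_domain = expand.grid(
        mean_angle = seq(-90, 90, by = mean_angle_step),
        ext_noise_sd = c(0, 30, 48, 64, 80, 96, 112, 128)),
      grids = list(sigma_int = exp(seq(log(1), log(40), length.out = 25)),
                   exponent = seq(0, 1, length.out = 21),
                   midpoint = seq(-20, 20, length.out = 21)),
      interest = c("sigma_int", "exponent"),
      response_labels = c("left", "right")),
    "3" = list(
      conditions = data.frame(condition = 1:6,
                              set_size = rep(c(1L, 9L, 25L), 2),
                              congruent = rep(c(TRUE, FALSE), each = 3)),
      n_staircase = 52L, n_catch = 4L,
      catch = data.frame(amplitude = 0.2),
      run_length = 42L, n_runs = 8L,
      stimulus_domain = data.frame(
        amplitude = exp(seq(log(0.01), log(0.2), length.out = n_amplitudes))),
      grids = list(alpha = exp(seq(log(0.01), log(0.2), length.out = 31)),
                   beta = exp(seq(log(0.5), log(16), length.out = 15))),
      interest = "alpha",
      response_labels = c("incorrect", "correct")),
    stop("'experiment' must be 1, 2 or 3"))
  cfg$experiment <- experiment
  cfg$lapse <- lapse
  cfg$tau <- tau
  class(cfg) <- "exp_config"
  cfg
}

#' @export
print.exp_config <- function(x, ...) {
  tot <- nrow(x$conditions) * (x$n_staircase + x$n_catch)
  cat(sprintf(
    "<exp_config> experiment %d: %d conditions x (%d staircase + %d catch) = %d trials, %d runs of %d\n",
    x$experiment, nrow(x$conditions), x$n_staircase, x$n_catch, tot,
    x$n_runs, x$run_length))
  invisible(x)
}

#' Build the staircase lattice for one condition of a design
#'
#' The likelihood is the design's psychometric family with the
#' configuration's fixed lapse: cumulative Normal (experiment 1), wrapped
#' cumulative Normal with the equivalent-noise spread and N =
#' set_size^exponent (experiment 2), or 2AFC Weibull (experiment 3).
#'
#' @param config an [exp_config()].
#' @param condition condition index (only matters for experiment 2, where
#'   the set size enters the likelihood).
#' @return a [psi_lattice()].
#' @export
make_psi_lattice <- function(config, condition = 1L) {
  stopifnot(inherits(config, "exp_config"))
  lapse <- config$lapse
  lik <- switch(as.character(config$experiment),
    "1" = function(stim, nodes) {
      pf_cnorm(stim$mean_angle, nodes$midpoint, nodes$spread, lapse)
    },
    "2" = {
      ss <- config$conditions$set_size[condition]
      function(stim, nodes) {
        pf_wrapped_cnorm(stim$mean_angle, nodes$midpoint,
                         en_spread(nodes$sigma_int, stim$ext_noise_sd,
                                   pmax(1, ss^nodes$exponent)), lapse)
      }
    },
    "3" = function(stim, nodes) {
      pf_weibull(stim$amplitude, nodes$alpha, nodes$beta, 0.5, lapse)
    })
  psi_lattice(config$grids, config$interest, config$stimulus_domain, lik,
              tau = config$tau, response_labels = config$response_labels)
}

#' Build a randomly interleaved session plan
#'
#' Per condition, the reference staircase and catch trial counts; trials are
#' randomly interleaved across the whole session (using the current RNG
#' stream) and split into the design's runs. Catch trials carry the reference
#' catch level, with a random sign for angular catches.
#'
#' @param config an [exp_config()].
#' @return data.frame with columns `trial`, `run`, `condition`, `is_catch`
#'   plus the catch stimulus columns (NA on staircase trials).
#' @export
build_session_plan <- function(config) {
  stopifnot(inherits(config, "exp_config"))
  nc <- nrow(config$conditions)
  per <- config$n_staircase + config$n_catch
  total <- nc * per
  if (total %% config$run_length != 0 ||
      total != config$n_runs * config$run_length) {
    stop("trial counts (", total, ") do not divide into ", config$n_runs,
         " runs of ", config$run_length)
  }
  plan <- data.frame(
    condition = rep(config$conditions$condition, each = per),
    is_catch = rep(rep(c(FALSE, TRUE),
                       c(config$n_staircase, config$n_catch)), nc))
  plan <- plan[sample.int(total), , drop = FALSE]
  plan$trial <- seq_len(total)
  plan$run <- rep(seq_len(config$n_runs), each = config$run_length)
  for (cn in names(config$catch)) {
    lev <- config$catch[[cn]]
    val <- rep(NA_real_, total)
    if (cn == "mean_angle") {
      val[plan$is_catch] <- lev * sample(c(-1, 1), sum(plan$is_catch),
                                         replace = TRUE)
    } else {
      val[plan$is_catch] <- lev
    }
    plan[[paste0("catch_", cn)]] <- val
  }
  rownames(plan) <- NULL
  plan[, c("trial", "run", "condition", "is_catch",
           grep("^catch_", names(plan), value = TRUE))]
}

#' Simulate a full experimental session for one observer
#'
#' Runs the design end to end: one staircase per condition (interleaved per
#' the session plan), catch trials at the reference levels bypassing the
#' staircases, per-trial stimulus generation (per-object azimuths for the
#' direction tasks), observer responses, and staircase updates. Fully
#' deterministic given `seed`.
#'
#' @param config an [exp_config()].
#' @param obs an [observer()] (direction tasks) or [pf_observer()].
#' @param seed integer seed for the whole session.
#' @param participant participant identifier stored in the log.
#' @param lattices optional list of prebuilt per-condition lattices (reset
#'   before use); avoids recomputing likelihood tables across participants.
#' @return a trial-log data.frame (one row per trial; see
#'   [write_trial_log()] for the schema) with attribute `psi_estimates`, a
#'   data.frame of final per-condition marginal posterior summaries.
#' @export
simulate_session <- function(config, obs, seed, participant = "p1",
                             lattices = NULL) {
  stopifnot(inherits(config, "exp_config"))
  set.seed(.subseed(seed, 101))
  if (is.null(lattices)) {
    lattices <- lapply(config$conditions$condition,
                       function(cc) make_psi_lattice(config, cc))
  } else {
    lattices <- lapply(lattices, psi_reset)
  }
  plan <- build_session_plan(config)
  n <- nrow(plan)
  cond <- config$conditions
  exp_n <- config$experiment
  rec <- list(
    mean_angle = rep(NA_real_, n), ext_noise_sd = rep(NA_real_, n),
    amplitude = rep(NA_real_, n), azim = rep(NA_character_, n),
    response = rep(NA_character_, n), correct = rep(NA, n))
  for (i in seq_len(n)) {
    ci <- plan$condition[i]
    crow <- cond[cond$condition == ci, ]
    if (exp_n %in% c(1, 2)) {
      if (plan$is_catch[i]) {
        stim <- data.frame(mean_angle = plan$catch_mean_angle[i],
                           ext_noise_sd = 0)
      } else {
        stim <- psi_select(lattices[[ci]])
        if (is.null(stim$ext_noise_sd)) stim$ext_noise_sd <- 0
      }
      ss <- crow$set_size
      if (inherits(obs, "pf_observer")) {
        pars <- obs$params[obs$params$condition == ci, ]
        p <- pf_cnorm(stim$mean_angle, pars$midpoint, pars$spread, pars$lapse)
        resp <- if (stats::runif(1) < p) "right" else "left"
        az <- assign_azimuths(stim$mean_angle, stim$ext_noise_sd, ss)
      } else {
        tr <- sim_direction_trials(obs, stim$mean_angle, stim$ext_noise_sd, ss)
        resp <- tr$response
        az <- if (is.null(tr$azimuths)) {
          assign_azimuths(stim$mean_angle, stim$ext_noise_sd, ss)
        } else as.vector(tr$azimuths)
      }
      rec$mean_angle[i] <- stim$mean_angle
      rec$ext_noise_sd[i] <- stim$ext_noise_sd
      rec$azim[i] <- as.character(jsonlite::toJSON(az, digits = NA))
      rec$response[i] <- resp
      rec$correct[i] <- if (stim$mean_angle == 0) NA else
        (resp == "right") == (stim$mean_angle > 0)
      if (!plan$is_catch[i]) {
        lattices[[ci]] <- psi_update(lattices[[ci]],
                                     stim[names(config$stimulus_domain)],
                                     resp)
      }
    } else {
      amp <- if (plan$is_catch[i]) plan$catch_amplitude[i] else
        psi_select(lattices[[ci]])$amplitude
      pars <- obs$params[obs$params$condition == ci, ]
      resp <- simulate_shape_response(amp, pars$alpha, pars$beta,
                                      pars$guess, pars$lapse)
      rec$amplitude[i] <- amp
      rec$response[i] <- resp
      rec$correct[i] <- resp == "correct"
      if (!plan$is_catch[i]) {
        lattices[[ci]] <- psi_update(lattices[[ci]],
                                     data.frame(amplitude = amp), resp)
      }
    }
  }
  log <- data.frame(
    participant = participant, experiment = exp_n,
    run = plan$run, trial = plan$trial, condition = plan$condition,
    set_size = cond$set_size[match(plan$condition, cond$condition)],
    shadows = if (!is.null(cond$shadows))
      cond$shadows[match(plan$condition, cond$condition)] else NA,
    congruent = if (!is.null(cond$congruent))
      cond$congruent[match(plan$condition, cond$condition)] else NA,
    mean_angle = rec$mean_angle, ext_noise_sd = rec$ext_noise_sd,
    amplitude = rec$amplitude, per_object_azimuths = rec$azim,
    response = rec$response, correct = rec$correct,
    is_catch = plan$is_catch)
  est <- do.call(rbind, lapply(seq_along(lattices), function(k) {
    e <- psi_estimates(lattices[[k]])
    e$condition <- config$conditions$condition[k]
    e$participant <- participant
    e
  }))
  attr(log, "psi_estimates") <- est
  attr(log, "lattices") <- lattices
  log
}

#' Simulate a cohort of observers through the same design
#'
#' Staircase likelihood tables are built once and reused (reset) across
#' participants. Seeds per participant are derived from `seed`.
#'
#' @param config an [exp_config()].
#' @param observers named list of observers; names become participant ids
#'   (unnamed lists get "p1", "p2", ...).
#' @param seed integer base seed.
#' @return list with `log` (row-bound trial logs) and `psi_estimates`
#'   (row-bound per-participant staircase summaries).
#' @export
simulate_cohort <- function(config, observers, seed) {
  if (is.null(names(observers))) {
    names(observers) <- paste0("p", seq_along(observers))
  }
  lattices <- lapply(config$conditions$condition,
                     function(cc) make_psi_lattice(config, cc))
  logs <- vector("list", length(observers))
  ests <- vector("list", length(observers))
  for (k in seq_along(observers)) {
    l <- simulate_session(config, observers[[k]], seed = .subseed(seed, k),
                          participant = names(observers)[k],
                          lattices = lattices)
    ests[[k]] <- attr(l, "psi_estimates")
    attr(l, "psi_estimates") <- NULL
    attr(l, "lattices") <- NULL
    logs[[k]] <- l
  }
  list(log = do.call(rbind, logs), psi_estimates = do.call(rbind, ests))
}

#' Simulate a non-adaptive (random-placement) direction session
#'
#' Stimuli are drawn uniformly from a stimulus domain instead of being
#' placed by a staircase. Statistically convenient for analyses that only
#' need broad stimulus coverage (e.g. the object-reliance residual
#' analysis) at a fraction of the cost of the adaptive procedure.
#'
#' @param obs an [observer()].
#' @param n_trials number of trials.
#' @param set_size objects per scene.
#' @param stimulus_domain data.frame with `mean_angle` and `ext_noise_sd`
#'   columns to sample from (default: the experiment-2 domain restricted to
#'   non-zero external noise).
#' @param seed integer seed.
#' @param participant participant id for the log.
#' @return a trial-log data.frame in the standard schema.
#' @export
simulate_random_design <- function(obs, n_trials, set_size,
                                   stimulus_domain = NULL, seed = 1,
                                   participant = "p1") {
  stopifnot(inherits(obs, "en_observer"))
  if (is.null(stimulus_domain)) {
    d <- exp_config(2)$stimulus_domain
    stimulus_domain <- d[d$ext_noise_sd > 0, ]
  }
  set.seed(.subseed(seed, 202))
  pick <- sample.int(nrow(stimulus_domain), n_trials, replace = TRUE)
  ma <- stimulus_domain$mean_angle[pick]
  en <- stimulus_domain$ext_noise_sd[pick]
  tr <- sim_direction_trials(obs, ma, en, set_size)
  az <- tr$azimuths
  if (is.null(az)) {
    az <- matrix(wrap_angle(stats::rnorm(n_trials * set_size,
                                         rep(ma, set_size),
                                         rep(en, set_size))),
                 nrow = n_trials)
  }
  azs <- vapply(seq_len(n_trials), function(i)
    as.character(jsonlite::toJSON(az[i, ], digits = NA)), character(1))
  data.frame(
    participant = participant, experiment = 2L, run = NA_integer_,
    trial = seq_len(n_trials), condition = 1L, set_size = set_size,
    shadows = NA, congruent = NA, mean_angle = ma, ext_noise_sd = en,
    amplitude = NA_real_, per_object_azimuths = azs,
    response = tr$response,
    correct = ifelse(ma == 0, NA, (tr$response == "right") == (ma > 0)),
    is_catch = FALSE)
}

.log_schema <- c("participant", "experiment", "run", "trial", "condition",
                 "set_size", "shadows", "congruent", "mean_angle",
                 "ext_noise_sd", "amplitude", "per_object_azimuths",
                 "response", "correct", "is_catch")

#' Write a trial log to CSV
#'
#' One row per trial; per-object azimuths are stored as a JSON-encoded list
#' in the `per_object_azimuths` column so the round trip is lossless.
#'
#' @param log trial-log data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  miss <- setdiff(.log_schema, names(log))
  if (length(miss)) stop("log is missing column(s): ",
                         paste(miss, collapse = ", "))
  utils::write.csv(log[, .log_schema], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial log from CSV
#'
#' Validates the schema: all columns present, responses in the known
#' alphabet, and per-object azimuth lists matching the set size on
#' direction-task rows. Errors name the offending column or row.
#'
#' @param path CSV path written by [write_trial_log()].
#' @return trial-log data.frame.
#' @export
read_trial_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(per_object_azimuths = "character",
                                        participant = "character"))
  miss <- setdiff(.log_schema, names(log))
  if (length(miss)) stop("trial log is missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!log$response %in% c("left", "right", "correct", "incorrect"))
  if (length(bad)) stop("invalid response value at row ", bad[1])
  dir_rows <- which(log$experiment %in% c(1L, 2L) &
                      nzchar(log$per_object_azimuths))
  for (i in dir_rows) {
    az <- jsonlite::fromJSON(log$per_object_azimuths[i])
    if (length(az) != log$set_size[i]) {
      stop("per_object_azimuths length (", length(az),
           ") does not match set_size (", log$set_size[i], ") at row ", i)
    }
  }
  log$shadows <- as.logical(log$shadows)
  log$congruent <- as.logical(log$congruent)
  log$correct <- as.logical(log$correct)
  log$is_catch <- as.logical(log$is_catch)
  log
}

#' Parse the per-object azimuths of a trial log into a matrix
#'
#' @param log trial-log data.frame (all rows must share one set size).
#' @return trials x set_size numeric matrix, columns in layout order.
#' @export
azimuth_matrix <- function(log) {
  ss <- unique(log$set_size)
  if (length(ss) != 1) stop("log mixes set sizes; subset first")
  raw <- vapply(log$per_object_azimuths,
                function(s) as.numeric(jsonlite::fromJSON(s)), numeric(ss),
                USE.NAMES = FALSE)
  if (ss == 1L) matrix(raw, ncol = 1L) else t(raw)
}

#' Apply the participant exclusion screens
#'
#' Participants are excluded when catch-trial accuracy falls below
#' `catch_min` (strictly: accuracy of exactly 90% is retained), and - for
#' the equivalent-noise design - when their internal-noise estimate exceeds
#' `sigma_int_max` (strictly greater; an estimate of exactly 25 is
#' retained). The internal-noise estimate is the marginal posterior median
#' from the participant's own staircase lattices, averaged over conditions
#' (pass it via `sigma_int`, e.g. from `psi_estimates` of
#' [simulate_cohort()] or from [fit_en_pointwise()]).
#'
#' @param log trial-log data.frame containing catch trials.
#' @param sigma_int optional named vector of per-participant internal-noise
#'   estimates (degrees).
#' @param catch_min catch accuracy threshold (default 0.9).
#' @param sigma_int_max internal-noise threshold in degrees (default 25).
#' @return list with `included` (character vector of participant ids) and
#'   `report` (per-participant data.frame with accuracy, estimates, and the
#'   exclusion reason, "" if retained).
#' @export
apply_exclusions <- function(log, sigma_int = NULL, catch_min = 0.9,
                             sigma_int_max = 25) {
  parts <- unique(log$participant)
  rep_list <- lapply(parts, function(p) {
    sub <- log[log$participant == p & log$is_catch, ]
    if (nrow(sub) == 0) stop("participant ", p, " has no catch trials")
    acc <- mean(sub$correct, na.rm = TRUE)
    si <- if (!is.null(sigma_int)) unname(sigma_int[p]) else NA_real_
    reason <- ""
    if (acc < catch_min) {
      reason <- sprintf("catch accuracy %.1f%% < %.0f%%", 100 * acc,
                        100 * catch_min)
    } else if (!is.na(si) && si > sigma_int_max) {
      reason <- sprintf("internal noise %.1f deg > %.0f deg", si,
                        sigma_int_max)
    }
    data.frame(participant = p, catch_accuracy = acc, sigma_int = si,
               excluded = nzchar(reason), reason = reason)
  })
  report <- do.call(rbind, rep_list)
  list(included = report$participant[!report$excluded], report = report)
}
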