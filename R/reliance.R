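# Residual-based object-reliance attribution. The fitted equivalent-noise
# model predicts rightwards-judgement probabilities from the *mean*
# illumination angle; if an observer in fact relies on a particular object,
# the model under-predicts "right" when that object is lit from the right
# and over-predicts when it is lit from the left. Signing the residuals by
# the object's own illumination angle and averaging over angle bins turns
# that pattern into a per-object reliance score, compared against a
# posterior-predictive reference band of scores expected under the model.

#' Per-trial, per-draw model residuals
#'
#' Residual = observed rightwards indicator minus the model probability of
#' a rightwards judgement, for every retained posterior draw. Restricted to
#' non-catch trials with external noise greater than zero (only there do
#' individual objects carry angles different from the mean).
#'
#' @param fit an `en_fit` for the equivalent-noise design ([fit_exp2()] or
#'   [fit_en_pointwise()]).
#' @param log optional trial log (default: the fitted log); participants
#'   must all appear in the fit.
#' @param draw_ids posterior draws to use (default: up to 100).
#' @return object of class `en_residuals`: list with `log` (the analysed
#'   subset), `res` (trials x draws residual matrix) and `phat` (matched
#'   probabilities).
#' @export
compute_residuals <- function(fit, log = NULL, draw_ids = NULL) {
  stopifnot(inherits(fit, "en_fit"), fit$experiment == 2L)
  if (is.null(log)) log <- fit$log
  log <- log[log$experiment == 2L & !log$is_catch & log$ext_noise_sd > 0, ,
             drop = FALSE]
  if (nrow(log) == 0) stop("no external-noise trials to analyse")
  if (!all(unique(log$participant) %in% fit$participants)) {
    stop("trial log contains participants absent from the fit")
  }
  phat <- predict(fit, log, draw_ids = draw_ids)
  y <- as.numeric(log$response == "right")
  structure(list(log = log, res = y - phat, phat = phat),
            class = "en_residuals")
}

#' @export
print.en_residuals <- function(x, ...) {
  cat(sprintf("<en_residuals> %d trials x %d draws\n",
              nrow(x$res), ncol(x$res)))
  invisible(x)
}

.bin_index <- function(az, n_bins) {
  pmin(pmax(ceiling((az + 180) / (360 / n_bins)), 1L), n_bins)
}

# core: per-object binned signed-residual means and summary scores for one
# set-size subset. `res` is trials x draws; `az` trials x objects.
.object_scores <- function(res, az, n_bins) {
  n_obj <- ncol(az)
  D <- ncol(res)
  scores <- matrix(NA_real_, n_obj, D)
  bins <- vector("list", n_obj)
  for (o in seq_len(n_obj)) {
    b <- .bin_index(az[, o], n_bins)
    flip <- ifelse(az[, o] < 0, -1, 1)
    counts <- tabulate(b, nbins = n_bins)
    bm <- rowsum(res * flip, b, reorder = TRUE)
    full <- matrix(NA_real_, n_bins, D)
    full[sort(unique(b)), ] <- bm / counts[sort(unique(b))]
    scores[o, ] <- colMeans(full, na.rm = TRUE)
    bins[[o]] <- full
  }
  list(scores = scores, bins = bins)
}

#' Per-object reliance summaries
#'
#' For each object position (layout order: 1 = centre, then inner ring,
#' then outer ring): residuals are binned by that object's trial-specific
#' illumination angle, their sign is reversed where the angle is negative,
#' bin means are averaged (unweighted across non-empty bins, or
#' trial-weighted if `weight_bins_by_trials`) into a summary score, and
#' credible intervals are taken across posterior draws. Empty angle bins
#' are dropped with a warning. Trials are pooled within each set-size
#' condition and reported per set size.
#'
#' @param resid an [compute_residuals()] object.
#' @param n_bins angle bins over (-180, 180] (default 12, i.e. 30-degree
#'   bins).
#' @param level credible level for the score intervals.
#' @param weight_bins_by_trials if TRUE, average residuals over trials
#'   directly instead of equally over bins.
#' @return object of class `reliance_summary`: data.frame with columns
#'   `set_size`, `object`, `score` (posterior median), `lower`, `upper`;
#'   attribute `bins` holds the per-object binned means.
#' @export
object_summary <- function(resid, n_bins = 12, level = 0.95,
                           weight_bins_by_trials = FALSE) {
  stopifnot(inherits(resid, "en_residuals"))
  qs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  out <- list(); bins_all <- list()
  for (ss in sort(unique(resid$log$set_size))) {
    sel <- resid$log$set_size == ss
    az <- azimuth_matrix(resid$log[sel, ])
    res <- resid$res[sel, , drop = FALSE]
    if (weight_bins_by_trials) {
      n_obj <- ncol(az)
      sc <- vapply(seq_len(n_obj), function(o) {
        flip <- ifelse(az[, o] < 0, -1, 1)
        colMeans(res * flip)
      }, numeric(ncol(res)))
      sc <- t(sc)
      os <- list(scores = sc, bins = NULL)
    } else {
      os <- .object_scores(res, az, n_bins)
      n_empty <- sum(vapply(os$bins,
                            function(b) sum(is.na(b[, 1])), numeric(1)))
      if (n_empty > 0) {
        warning(n_empty, " empty angle bin(s) dropped (set size ", ss, ")")
      }
    }
    q <- t(apply(os$scores, 1, stats::quantile, probs = qs, names = FALSE))
    out[[length(out) + 1]] <- data.frame(
      set_size = ss, object = seq_len(nrow(q)),
      score = q[, 2], lower = q[, 1], upper = q[, 3])
    bins_all[[as.character(ss)]] <- os$bins
  }
  res_df <- do.call(rbind, out)
  attr(res_df, "bins") <- bins_all
  attr(res_df, "n_bins") <- n_bins
  class(res_df) <- c("reliance_summary", "data.frame")
  res_df
}

#' Posterior-predictive reference band for reliance scores
#'
#' Recomputes the object summaries with responses *generated from the
#' fitted model* (one posterior draw per replicate) in place of the
#' observed responses, giving the distribution of scores expected if the
#' equivalent-noise model were the whole story. Returns pointwise
#' `level` intervals per object and Bonferroni-adjusted simultaneous
#' intervals (familywise `level` across the objects of a set size), the
#' latter being the recommended flagging criterion.
#'
#' @param resid an [compute_residuals()] object.
#' @param n_replicates model-generated replicate datasets (default 400).
#' @param n_bins as in [object_summary()].
#' @param level band level (default 0.95).
#' @param seed seed for the replicate simulations.
#' @return data.frame with columns `set_size`, `object`, `lower`, `upper`,
#'   `lower_sim`, `upper_sim`.
#' @export
reference_band <- function(resid, n_replicates = 400, n_bins = 12,
                           level = 0.95, seed = 1) {
  stopifnot(inherits(resid, "en_residuals"))
  set.seed(.subseed(seed, 515))
  D <- ncol(resid$phat)
  out <- list()
  for (ss in sort(unique(resid$log$set_size))) {
    sel <- resid$log$set_size == ss
    az <- azimuth_matrix(resid$log[sel, ])
    ph <- resid$phat[sel, , drop = FALSE]
    n <- nrow(az); n_obj <- ncol(az)
    # precompute per-object bin indices, flips and counts once
    binfo <- lapply(seq_len(n_obj), function(o) {
      b <- .bin_index(az[, o], n_bins)
      list(b = b, flip = ifelse(az[, o] < 0, -1, 1),
           counts = tabulate(b, nbins = n_bins),
           used = sort(unique(b)))
    })
    scores <- matrix(NA_real_, n_obj, n_replicates)
    for (r in seq_len(n_replicates)) {
      d <- ((r - 1) %% D) + 1
      ysim <- stats::rbinom(n, 1, ph[, d])
      rsim <- ysim - ph[, d]
      for (o in seq_len(n_obj)) {
        bi <- binfo[[o]]
        bm <- rowsum(rsim * bi$flip, bi$b, reorder = TRUE)
        scores[o, r] <- mean(bm[, 1] / bi$counts[bi$used])
      }
    }
    a <- (1 - level) / 2
    a_sim <- a / n_obj
    q <- t(apply(scores, 1, stats::quantile,
                 probs = c(a, 1 - a, a_sim, 1 - a_sim), names = FALSE))
    out[[length(out) + 1]] <- data.frame(
      set_size = ss, object = seq_len(n_obj),
      lower = q[, 1], upper = q[, 2],
      lower_sim = q[, 3], upper_sim = q[, 4])
  }
  do.call(rbind, out)
}

#' Flag objects whose reliance score exceeds the reference band
#'
#' @param summary a [object_summary()] result.
#' @param band a [reference_band()] result.
#' @param simultaneous use the Bonferroni simultaneous band (default TRUE);
#'   FALSE compares against the pointwise band.
#' @return the summary data.frame with band columns and a logical
#'   `above_band` column merged in.
#' @export
reliance_flags <- function(summary, band, simultaneous = TRUE) {
  m <- merge(as.data.frame(summary), band, by = c("set_size", "object"))
  hi <- if (simultaneous) m$upper_sim else m$upper.y
  m$above_band <- m$score > hi
  m[order(m$set_size, m$object), ]
}

#' @export
plot.reliance_summary <- function(x, band = NULL, ...) {
  sss <- unique(x$set_size)
  oldpar <- graphics::par(mfrow = c(length(sss), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  for (ss in sss) {
    s <- x[x$set_size == ss, ]
    graphics::plot(s$object, s$score, pch = 19,
                   ylim = range(c(s$lower, s$upper, 0), na.rm = TRUE),
                   xlab = "object (layout order; 1 = centre)",
                   ylab = "reliance score",
                   main = paste("set size", ss), ...)
    graphics::arrows(s$object, s$lower, s$object, s$upper, angle = 90,
                     code = 3, length = 0.03)
    if (!is.null(band)) {
      b <- band[band$set_size == ss, ]
      graphics::rect(b$object - 0.4, b$lower, b$object + 0.4, b$upper,
                     col = grDevices::adjustcolor("grey", 0.4), border = NA)
    }
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
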