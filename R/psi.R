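# Psi-marginal adaptive staircase: a discretised posterior over psychometric
# parameters, expected-posterior-entropy stimulus selection with nuisance
# marginalisation, and the stimulus constraints used in the reference designs
# (similarly-informative selection sets, sign-flip rule for runs).

#' Construct a Psi-marginal staircase lattice
#'
#' The staircase state is a discrete posterior over the Cartesian product of
#' named 1-D parameter grids, together with a stimulus domain and the
#' psychometric likelihood connecting them. Dimensions named in `interest`
#' are targeted by stimulus selection; the rest are nuisance and are
#' marginalised out before entropies are computed.
#'
#' @param grids named list of numeric parameter grids (e.g.
#'   `list(spread = ..., midpoint = ...)`).
#' @param interest character vector naming the grid dimensions of interest.
#' @param stimulus_domain data.frame of admissible stimuli (one column per
#'   stimulus dimension, e.g. `mean_angle`, `ext_noise_sd`).
#' @param likelihood_fn function(stimulus, nodes) returning, for a one-row
#'   stimulus and the full node data.frame, the probability of the
#'   *positive* response (second element of `response_labels`) at every node.
#' @param prior optional prior mass over nodes (default uniform); any
#'   non-negative vector, renormalised.
#' @param tau "similarly informative" tolerance: stimuli whose expected
#'   entropy is within `tau` times the entropy range of the minimum form
#'   the selection set (default 0.05).
#' @param response_labels length-2 character vector, negative then positive
#'   response (default `c("left", "right")`).
#' @return an object of class `psi_lattice`.
#' @export
psi_lattice <- function(grids, interest, stimulus_domain, likelihood_fn,
                        prior = NULL, tau = 0.05,
                        response_labels = c("left", "right")) {
  stopifnot(is.list(grids), length(names(grids)) == length(grids),
            all(interest %in% names(grids)),
            is.data.frame(stimulus_domain), nrow(stimulus_domain) >= 1)
  if (anyDuplicated(stimulus_domain)) stop("duplicate stimuli in domain")
  nodes <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  G <- nrow(nodes)
  if (is.null(prior)) prior <- rep(1 / G, G)
  if (length(prior) != G || any(prior < 0) || sum(prior) <= 0) {
    stop("'prior' must be a non-negative vector over all ", G, " nodes")
  }
  prior <- prior / sum(prior)
  int_levels <- unique(nodes[, interest, drop = FALSE])
  interest_idx <- match(
    do.call(paste, nodes[, interest, drop = FALSE]),
    do.call(paste, int_levels))
  # precompute the likelihood of the positive response for every
  # (stimulus, node) pair; this is fixed for the lifetime of the lattice
  S <- nrow(stimulus_domain)
  L <- matrix(NA_real_, G, S)
  for (s in seq_len(S)) {
    L[, s] <- likelihood_fn(stimulus_domain[s, , drop = FALSE], nodes)
  }
  if (any(!is.finite(L)) || any(L < 0) || any(L > 1)) {
    stop("likelihood_fn must return probabilities in [0, 1]")
  }
  # reorder nodes as (nuisance fastest, interest slowest) so marginalising
  # the nuisance dimensions is a single colSums pass at selection time
  nuis <- setdiff(names(grids), interest)
  nuis_idx <- if (length(nuis)) {
    nuis_levels <- unique(nodes[, nuis, drop = FALSE])
    match(do.call(paste, nodes[, nuis, drop = FALSE]),
          do.call(paste, nuis_levels))
  } else rep(1L, G)
  node_order <- order(interest_idx, nuis_idx)
  structure(list(
    grids = grids, interest = interest, nodes = nodes,
    interest_idx = interest_idx, interest_levels = int_levels,
    node_order = node_order, n_interest = nrow(int_levels),
    n_nuisance = max(nuis_idx),
    Lr = L[node_order, , drop = FALSE],
    stimulus_domain = stimulus_domain, L = L,
    prior = prior, posterior = prior,
    tau = tau, response_labels = response_labels,
    hist_stim = integer(64), hist_resp = character(64), n_hist = 0L),
    class = "psi_lattice")
}

#' @export
print.psi_lattice <- function(x, ...) {
  cat(sprintf(
    "<psi_lattice> %d nodes (%s), %d stimuli, %d trial(s) observed\n",
    nrow(x$nodes), paste(names(x$grids), collapse = " x "),
    nrow(x$stimulus_domain), x$n_hist))
  invisible(x)
}

.stim_index <- function(lat, stimulus) {
  dom <- lat$stimulus_domain
  stimulus <- as.data.frame(stimulus)
  ok <- rep(TRUE, nrow(dom))
  for (cn in names(dom)) {
    if (is.null(stimulus[[cn]])) stop("stimulus is missing component '", cn, "'")
    ok <- ok & abs(dom[[cn]] - stimulus[[cn]]) < 1e-9
  }
  idx <- which(ok)
  if (length(idx) != 1) stop("stimulus not in the lattice's stimulus domain")
  idx
}

#' Bayesian update of the staircase posterior
#'
#' Multiplies the current posterior mass by the likelihood of the observed
#' response at every grid node and renormalises; the trial is appended to
#' the history.
#'
#' @param lat a `psi_lattice`.
#' @param stimulus a one-row data.frame (or named list) matching the
#'   stimulus-domain columns; must be an element of the domain.
#' @param response one of the lattice's `response_labels`.
#' @return the updated `psi_lattice`.
#' @export
psi_update <- function(lat, stimulus, response) {
  stopifnot(inherits(lat, "psi_lattice"))
  if (!response %in% lat$response_labels) {
    stop("response must be one of: ",
         paste(lat$response_labels, collapse = ", "))
  }
  s <- .stim_index(lat, stimulus)
  p_pos <- lat$L[, s]
  lik <- if (response == lat$response_labels[2]) p_pos else 1 - p_pos
  post <- lat$posterior * lik
  z <- sum(post)
  if (z <= 0) stop("posterior mass vanished: response has zero likelihood everywhere")
  lat$posterior <- post / z
  n <- lat$n_hist + 1L
  if (n > length(lat$hist_stim)) {   # amortised growth
    lat$hist_stim <- c(lat$hist_stim, integer(length(lat$hist_stim)))
    lat$hist_resp <- c(lat$hist_resp, character(length(lat$hist_resp)))
  }
  lat$hist_stim[n] <- s
  lat$hist_resp[n] <- response
  lat$n_hist <- n
  lat
}

#' Trial history of a staircase
#'
#' The ordered (stimulus, response) pairs observed so far; every stimulus
#' is an element of the lattice's stimulus domain.
#'
#' @param lat a `psi_lattice`.
#' @return data.frame of the stimulus columns plus `response`.
#' @export
psi_history <- function(lat) {
  stopifnot(inherits(lat, "psi_lattice"))
  idx <- lat$hist_stim[seq_len(lat$n_hist)]
  out <- cbind(lat$stimulus_domain[idx, , drop = FALSE],
               data.frame(response = lat$hist_resp[seq_len(lat$n_hist)]))
  rownames(out) <- NULL
  out
}

.marginal_entropy <- function(mass_by_interest) {
  # columns: candidate stimuli; rows: interest levels. Each column holds
  # *unnormalised* joint mass of (interest level, response); entropy of the
  # normalised column in bits (0 log 0 = 0), computed without normalising
  # the matrix: H = log2(Z) - sum(m log2 m)/Z.
  tiny <- .Machine$double.xmin
  Z <- pmax(colSums(mass_by_interest), tiny)
  slog <- colSums(mass_by_interest *
                    log2(pmax(mass_by_interest, tiny)))
  log2(Z) - slog / Z
}

#' Expected posterior entropy of every candidate stimulus
#'
#' For each admissible stimulus, the expected Shannon entropy (bits) of the
#' post-trial posterior marginalised onto the interest dimensions, averaged
#' over the two possible responses with their predictive probabilities.
#' Stimulus selection minimises this quantity.
#'
#' @param lat a `psi_lattice`.
#' @return numeric vector, one expected entropy per stimulus-domain row.
#' @export
psi_expected_entropy <- function(lat) {
  stopifnot(inherits(lat, "psi_lattice"))
  I <- lat$n_interest; U <- lat$n_nuisance
  S <- nrow(lat$stimulus_domain)
  post_r <- lat$posterior[lat$node_order]
  PL <- lat$Lr * post_r                   # joint mass of (node, positive)
  dim(PL) <- c(U, I * S)
  M1 <- matrix(colSums(PL), I, S)         # nuisance marginalised out
  m_post <- colSums(matrix(post_r, U, I))
  M0 <- m_post - M1
  q1 <- colSums(M1)
  H1 <- .marginal_entropy(M1)
  H0 <- .marginal_entropy(M0)
  as.vector(q1 * H1 + (1 - q1) * H0)
}

.last_run_sign <- function(angles, k = 5) {
  n <- length(angles)
  if (n < k) return(0)
  last <- angles[(n - k + 1):n]
  s <- sign(last)
  if (all(s == 1)) 1 else if (all(s == -1)) -1 else 0
}

#' Select the next stimulus
#'
#' Computes the expected posterior entropy of every admissible stimulus,
#' forms the "similarly informative" set (within `tau` of the minimum,
#' relative to the entropy range), and samples uniformly from that set
#' using the current RNG stream. If the lattice's stimulus domain has a
#' `mean_angle` component and the five preceding trials all had mean angles
#' sharing the selected angle's sign, the selected angle's sign is flipped
#' (the run-breaking rule of the reference designs).
#'
#' @param lat a `psi_lattice`.
#' @param flip_run_length length of the same-sign run that triggers the
#'   sign flip (default 5; `Inf` disables the rule).
#' @return a one-row data.frame: the selected stimulus.
#' @export
psi_select <- function(lat, flip_run_length = 5) {
  stopifnot(inherits(lat, "psi_lattice"))
  if (nrow(lat$stimulus_domain) == 0) stop("empty stimulus domain")
  eh <- psi_expected_entropy(lat)
  rng <- range(eh)
  cand <- which(eh <= rng[1] + lat$tau * (rng[2] - rng[1]))
  pick <- cand[sample.int(length(cand), 1)]
  stim <- lat$stimulus_domain[pick, , drop = FALSE]
  if ("mean_angle" %in% names(stim) && is.finite(flip_run_length)) {
    hist_angles <- lat$stimulus_domain$mean_angle[
      lat$hist_stim[seq_len(lat$n_hist)]]
    run <- .last_run_sign(hist_angles, flip_run_length)
    if (run != 0 && sign(stim$mean_angle) == run) {
      flipped <- stim
      flipped$mean_angle <- -stim$mean_angle
      # only flip onto a stimulus that exists in the domain
      hit <- try(.stim_index(lat, flipped), silent = TRUE)
      if (!inherits(hit, "try-error")) {
        stim <- lat$stimulus_domain[hit, , drop = FALSE]
      }
    }
  }
  rownames(stim) <- NULL
  stim
}

#' Marginal posterior summaries over the interest dimensions
#'
#' Mean, median and SD of the marginal posterior of each interest dimension
#' (grid-weighted; the median is the smallest grid value whose cumulative
#' marginal mass reaches 0.5). Used for online monitoring and for the
#' internal-noise exclusion screen.
#'
#' @param lat a `psi_lattice`.
#' @return data.frame with one row per interest dimension: `parameter`,
#'   `mean`, `median`, `sd`.
#' @export
psi_estimates <- function(lat) {
  stopifnot(inherits(lat, "psi_lattice"))
  out <- lapply(lat$interest, function(nm) {
    m <- rowsum(lat$posterior, lat$nodes[[nm]], reorder = TRUE)
    vals <- as.numeric(rownames(m))
    w <- m[, 1] / sum(m[, 1])
    mu <- sum(vals * w)
    med <- vals[which(cumsum(w) >= 0.5)[1]]
    sdv <- sqrt(max(0, sum(vals^2 * w) - mu^2))
    data.frame(parameter = nm, mean = mu, median = med, sd = sdv)
  })
  do.call(rbind, out)
}

#' Reset a staircase to its prior
#'
#' Returns the lattice with posterior set back to the prior and history
#' cleared, keeping the (expensive) precomputed likelihood table, so one
#' lattice can be reused across simulated participants.
#'
#' @param lat a `psi_lattice`.
#' @return the reset `psi_lattice`.
#' @export
psi_reset <- function(lat) {
  stopifnot(inherits(lat, "psi_lattice"))
  lat$posterior <- lat$prior
  lat$n_hist <- 0L
  lat
}

#' Serialise staircase state to JSON
#'
#' Stores grids, interest set, stimulus domain, prior, posterior, tolerance,
#' response labels and history - everything except the likelihood function,
#' which must be supplied again on restore (functions do not serialise).
#'
#' @param lat a `psi_lattice`.
#' @param path optional file path.
#' @return JSON string (invisibly if written to `path`).
#' @export
psi_to_json <- function(lat, path = NULL) {
  stopifnot(inherits(lat, "psi_lattice"))
  state <- list(grids = lat$grids, interest = lat$interest,
                stimulus_domain = lat$stimulus_domain,
                prior = lat$prior, posterior = lat$posterior,
                tau = lat$tau, response_labels = lat$response_labels,
                history = psi_history(lat))
  j <- jsonlite::toJSON(state, dataframe = "columns", digits = NA,
                        auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}

#' Restore staircase state from JSON
#'
#' @param json JSON string or file path from [psi_to_json()].
#' @param likelihood_fn the psychometric likelihood used when the lattice
#'   was built (see [psi_lattice()]).
#' @return a `psi_lattice` with the stored posterior and history.
#' @export
psi_from_json <- function(json, likelihood_fn) {
  st <- jsonlite::fromJSON(json)
  lat <- psi_lattice(grids = st$grids, interest = st$interest,
                     stimulus_domain = as.data.frame(st$stimulus_domain),
                     likelihood_fn = likelihood_fn,
                     prior = st$prior, tau = st$tau,
                     response_labels = st$response_labels)
  lat$posterior <- st$posterior
  hist <- as.data.frame(st$history)
  if (nrow(hist) > 0) {
    lat$n_hist <- nrow(hist)
    lat$hist_resp <- hist$response
    lat$hist_stim <- vapply(seq_len(nrow(hist)), function(i)
      .stim_index(lat, hist[i, setdiff(names(hist), "response"),
                            drop = FALSE]), integer(1))
  }
  lat
}
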