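#' @title Synthetic trial-stream generator
#' @description
#' Generates multi-participant two-choice trial streams carrying exactly the
#' two relationships the inferential battery tests: per-trial mean RTs that
#' sit on the Devil's staircase at the drive Omega of the trial's depth-5
#' stimulus history, and error probabilities that grow with the history
#' ratio's denominator on the log-odds scale. The generative equations are
#' deliberately simple plumbing (linear-in-rho Gaussian RTs, logistic
#' errors); they exist so that scanning and statistics can be exercised and
#' parameter recovery asserted without any human data.
#' @name synth
NULL

#' Generator configuration
#'
#' @param n_participants Participants to simulate (default 8).
#' @param n_trials Trials per participant (default 4000).
#' @param schedule `"balanced"` (independent fair draws),
#'   `"repetition_biased"` (each trial repeats the previous stimulus with
#'   probability `bias`), or `"alternation_biased"` (alternates with
#'   probability `bias`).
#' @param bias Target proportion of biased pairs (default 2/3).
#' @param rt_intercept Baseline RT beta0 in ms (default 450).
#' @param rt_slope RT increase per unit rotation number, beta1 in ms
#'   (default 200).
#' @param rt_sd Gaussian RT noise sigma in ms (default 30).
#' @param error_base Error probability at the root denominator 2
#'   (default 0.05).
#' @param error_denom_slope Log-odds increment per denominator unit above 2
#'   (default 0.15).
#' @param rt_bounds Clipping bounds in ms (default `c(200, 980)`, so the
#'   scanner's censorship rules are exercised).
#' @param depth History depth used for generation (default 5).
#' @param seed Integer RNG seed (default 1).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 8L, n_trials = 4000L,
                         schedule = c("balanced", "repetition_biased", "alternation_biased"),
                         bias = 2 / 3, rt_intercept = 450, rt_slope = 200,
                         rt_sd = 30, error_base = 0.05, error_denom_slope = 0.15,
                         rt_bounds = c(200, 980), depth = 5L, seed = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(n_participants >= 1, n_trials >= depth, bias >= 0, bias <= 1,
            rt_sd >= 0, error_base >= 0, error_base <= 1,
            length(rt_bounds) == 2L, rt_bounds[1] < rt_bounds[2])
  structure(
    list(n_participants = as.integer(n_participants),
         n_trials = as.integer(n_trials), schedule = schedule, bias = bias,
         rt_intercept = rt_intercept, rt_slope = rt_slope, rt_sd = rt_sd,
         error_base = error_base, error_denom_slope = error_denom_slope,
         rt_bounds = rt_bounds, depth = as.integer(depth),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate one participant's stimulus schedule
#'
#' The first trial is a fair draw in every schedule.
#'
#' @param n_trials Number of trials.
#' @param schedule,bias As in [synth_config()].
#' @return Character vector of "R"/"L" stimulus identities.
#' @export
generate_schedule <- function(n_trials,
                              schedule = c("balanced", "repetition_biased", "alternation_biased"),
                              bias = 2 / 3) {
  schedule <- match.arg(schedule)
  if (schedule == "balanced") {
    return(sample(c("R", "L"), n_trials, replace = TRUE))
  }
  out <- character(n_trials)
  out[1] <- sample(c("R", "L"), 1L)
  keep <- stats::runif(n_trials - 1L) < bias
  for (t in seq_len(n_trials - 1L)) {
    same <- if (schedule == "repetition_biased") keep[t] else !keep[t]
    out[t + 1L] <- if (same) out[t] else c(R = "L", L = "R")[[out[t]]]
  }
  out
}

# drive value and denominator for every depth-5 stimulus window,
# via the Farey tree (R-leading) or Stern-Brocot duality (L-leading, wrapped)
window_lookup <- function(depth) {
  wins <- do.call(expand.grid, rep(list(c("R", "L")), depth))
  keys <- apply(wins, 1L, paste, collapse = "")
  info <- lapply(keys, function(h) {
    if (substr(h, 1L, 1L) == "R") {
      r <- history_to_ratio(h)
      c(omega = as.double(r), den = r$den)
    } else {
      r <- l_leading_ratio(h)
      c(omega = history_omega(h, wrap_l_leading = TRUE), den = r$den)
    }
  })
  m <- do.call(rbind, info)
  rownames(m) <- keys
  m
}

#' Generate responses and RTs over a stimulus schedule
#'
#' For each trial from `depth` on, the depth-long stimulus window ending at
#' the trial sets the drive Omega (R-leading ratio, or wrapped L-leading
#' value), the RT is `rt_intercept + rt_slope * rho(Omega) + N(0, rt_sd)`
#' clipped to `rt_bounds` with rho read off the supplied staircase, and an
#' error occurs with probability
#' `plogis(qlogis(error_base) + error_denom_slope * (denominator - 2))`.
#' Trials before `depth` use the root history (Omega = 1/2, denominator 2).
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param schedule Character vector of "R"/"L" stimuli.
#' @param config A [synth_config()].
#' @param staircase A [devils_staircase()] table at the model parameters.
#' @param participant Participant identifier for the output rows.
#' @return A trial-stream data.frame (`participant`, `trial`, `stimulus`,
#'   `response`, `correct`, `rt_ms`) with 0-based `trial`.
#' @export
generate_responses <- function(schedule, config, staircase, participant = 1L) {
  stopifnot(inherits(config, "synth_config"))
  n <- length(schedule)
  depth <- config$depth
  lut <- window_lookup(depth)
  omega <- rep(0.5, n)
  den <- rep(2, n)
  if (n >= depth) {
    keys <- vapply(depth:n, function(t) {
      paste(schedule[(t - depth + 1L):t], collapse = "")
    }, character(1))
    omega[depth:n] <- lut[keys, "omega"]
    den[depth:n] <- lut[keys, "den"]
  }
  rho <- staircase_lookup(staircase, omega)
  rt <- config$rt_intercept + config$rt_slope * rho +
    stats::rnorm(n, 0, config$rt_sd)
  rt <- pmin(pmax(rt, config$rt_bounds[1]), config$rt_bounds[2])
  p_err <- stats::plogis(stats::qlogis(config$error_base) +
                           config$error_denom_slope * (den - 2))
  if (config$error_base == 0) p_err <- rep(0, n)
  err <- stats::runif(n) < p_err
  response <- ifelse(err, c(R = "L", L = "R")[schedule], schedule)
  data.frame(
    participant = participant, trial = seq_len(n) - 1L, stimulus = schedule,
    response = unname(response), correct = as.integer(!err), rt_ms = rt,
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-participant trial stream
#'
#' Seeds the RNG once from `config$seed`; schedules, noise, and errors for
#' all participants are then drawn sequentially, so identical configs give
#' identical streams.
#'
#' @param config A [synth_config()].
#' @param staircase Optional precomputed [devils_staircase()] at the model
#'   defaults; computed here (0.001 grid, K = 0.95, A = 0.85) when NULL.
#' @return A trial-stream data.frame across all participants, with the
#'   clipping fraction in attribute `clip_fraction`.
#' @export
simulate_streams <- function(config = synth_config(), staircase = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  if (is.null(staircase)) staircase <- devils_staircase()
  parts <- lapply(seq_len(config$n_participants), function(p) {
    sched <- generate_schedule(config$n_trials, config$schedule, config$bias)
    generate_responses(sched, config, staircase, participant = p)
  })
  out <- do.call(rbind, parts)
  at_edge <- out$rt_ms %in% config$rt_bounds
  attr(out, "clip_fraction") <- mean(at_edge)
  out
}

#' End-to-end parameter recovery
#'
#' Runs generate -> scan -> statistics and reports whether the planted
#' staircase and denominator-error structures are detected: the staircase
#' r^2, the within-level Farey Spearman rho, and the sign of the
#' denominator-regression slope.
#'
#' @param config A [synth_config()].
#' @param staircase Optional precomputed staircase (see [simulate_streams()]).
#' @return A list with `staircase` and `spearman` `correlation_report`s,
#'   `denom_slope`, `clip_fraction`, and the scanned `grand` table.
#' @export
recovery_suite <- function(config = synth_config(), staircase = NULL) {
  if (is.null(staircase)) staircase <- devils_staircase(seed = config$seed)
  streams <- simulate_streams(config, staircase)
  scanned <- analyze_streams(streams, depth = config$depth,
                             bounds = config$rt_bounds)
  tree <- build_farey_tree(config$depth)
  st <- staircase_test(scanned$grand, staircase, tree)
  sp <- spearman_farey_test(scanned$grand, tree)
  dr <- denominator_regression(scanned$grand, tree)
  list(staircase = st, spearman = sp, denom_slope = dr$slope,
       clip_fraction = attr(streams, "clip_fraction"), grand = scanned$grand)
}
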