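#' @title Trial-stream IO and the full pipeline
#' @description
#' Trial streams travel as comma-delimited text with header
#' `participant,trial,stimulus,response,correct,rt_ms`. Correctness is
#' recomputed from stimulus/response on ingest and cross-checked against the
#' file's `correct` column; the recomputed value wins and mismatching rows
#' are reported. [run_pipeline()] binds the modules into one deterministic,
#' config-driven run that writes every table next to a provenance sidecar.
#' @name cli-io
NULL

#' Read a trial-stream CSV
#'
#' @param path CSV file with columns `participant`, `trial`, `stimulus`,
#'   `response`, `correct`, `rt_ms`.
#' @param drop_first_n Buffer trials to drop from the start of each
#'   participant's stream (default 0); trial indices are renumbered from 0.
#' @return A validated trial-stream data.frame.
#' @export
read_trials <- function(path, drop_first_n = 0L) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_stream(raw)
  recomputed <- as.integer(raw$stimulus == raw$response)
  mismatch <- which(recomputed != as.integer(raw$correct))
  if (length(mismatch)) {
    warning(sprintf("correct column disagrees with stimulus/response at row(s) %s; recomputed values used",
                    paste(utils::head(mismatch, 10L), collapse = ", ")),
            call. = FALSE)
    raw$correct <- recomputed
  }
  if (drop_first_n > 0L) {
    parts <- split(raw, raw$participant)
    raw <- do.call(rbind, lapply(parts, function(one) {
      one <- one[order(one$trial), , drop = FALSE]
      if (nrow(one) <= drop_first_n) {
        stop("drop_first_n removes all trials for participant ",
             one$participant[1], call. = FALSE)
      }
      one <- one[-seq_len(drop_first_n), , drop = FALSE]
      one$trial <- seq_len(nrow(one)) - 1L
      one
    }))
    rownames(raw) <- NULL
  }
  raw
}

#' Write a trial-stream CSV
#'
#' @param stream Trial-stream data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(stream, path) {
  check_stream(stream)
  utils::write.csv(stream[, c("participant", "trial", "stimulus", "response",
                              "correct", "rt_ms")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_run_config <- function() {
  list(
    K = 0.95, A = 0.85,
    omega_min = 0, omega_max = 1, omega_step = 0.001,
    n_iter = 10000L, n_avg = 2500L, n_keep = 100L, n_omega = 1000L,
    depth = 5L, rt_min = 200, rt_max = 980, mode = "terminal",
    l_leading = FALSE, drop_first_n = 0L,
    input = NULL, synth = list(), seed = 1L, bifurcation = FALSE
  )
}

#' Run the full analysis pipeline
#'
#' Staircase -> Farey tree -> trial stream (read from `config$input` or
#' simulated via `config$synth`) -> scan -> statistical battery, writing
#' every table (tab-separated) plus a provenance JSON (resolved config, seed,
#' package version) into `out_dir`. Deterministic given `config$seed`.
#'
#' @param config A named list, or the path to a YAML file, overriding the
#'   defaults: map parameters (`K`, `A`, `omega_min`, `omega_max`,
#'   `omega_step`, `n_iter`, `n_avg`, `n_keep`, `n_omega`, `bifurcation`),
#'   scan parameters (`depth`, `rt_min`, `rt_max`, `mode`, `l_leading`,
#'   `drop_first_n`), an `input` CSV path or a `synth` sublist of
#'   [synth_config()] arguments, and `seed`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the computed objects (`staircase`, `tree`,
#'   `streams`, `scanned`, `reports`) and `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("fareyscan_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  unknown <- setdiff(names(config), names(default_run_config()))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  grid <- seq(cfg$omega_min, cfg$omega_max, by = cfg$omega_step)
  staircase <- devils_staircase(K = cfg$K, A = cfg$A, omega = grid,
                                n_iter = cfg$n_iter, n_avg = cfg$n_avg,
                                seed = cfg$seed)
  write_staircase(staircase, file.path(out_dir, "staircase.tsv"))

  tree <- build_farey_tree(cfg$depth)
  write_farey_tree(tree, file.path(out_dir, "farey_tree.tsv"))

  if (isTRUE(cfg$bifurcation)) {
    surf <- bifurcation_surface(K = cfg$K, A = cfg$A, n_omega = cfg$n_omega,
                                n_iter = cfg$n_iter, n_keep = cfg$n_keep,
                                seed = cfg$seed)
    write_bifurcation(surf, file.path(out_dir, "bifurcation.tsv"))
  }

  if (!is.null(cfg$input)) {
    streams <- read_trials(cfg$input, drop_first_n = cfg$drop_first_n)
  } else {
    sc <- do.call(synth_config, utils::modifyList(list(seed = cfg$seed), cfg$synth))
    streams <- simulate_streams(sc, staircase)
    write_trials(streams, file.path(out_dir, "trials.csv"))
  }

  scanned <- analyze_streams(streams, depth = cfg$depth,
                             bounds = c(cfg$rt_min, cfg$rt_max),
                             mode = cfg$mode, l_leading = isTRUE(cfg$l_leading))
  write_history_stats(scanned$per_participant,
                      file.path(out_dir, "history_stats_per_participant.tsv"))
  write_history_stats(scanned$grand, file.path(out_dir, "history_stats_grand.tsv"))

  r_grand <- scanned$grand[substr(scanned$grand$history, 1, 1) == "R", ]
  reports <- list(
    staircase = staircase_test(r_grand, staircase, tree),
    spearman = spearman_farey_test(r_grand, tree)
  )
  dr <- denominator_regression(r_grand, tree)
  reports$denominator <- dr$report
  write_reports(reports, file.path(out_dir, "reports.tsv"))

  provenance <- list(
    package = "fareyscan",
    version = as.character(utils::packageVersion("fareyscan")),
    seed = cfg$seed,
    config = cfg[!vapply(cfg, is.null, logical(1))],
    denominator_slope = dr$slope
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(staircase = staircase, tree = tree, streams = streams,
                 scanned = scanned, reports = reports, out_dir = out_dir))
}
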