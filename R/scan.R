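#' @title Overlapping trial-history scanning
#' @description
#' A trial stream is one participant's ordered trial records (stimulus,
#' response, correctness, RT in ms). Every R stimulus is a potential sequence
#' origin: all overlapping windows whose STIMULUS sequence spells a history
#' are occurrences of that history, regardless of response accuracy —
#' correctness and censorship are separate flags, which is what lets
#' erroneous trials be members of a named sequence type. Mean RTs use only
#' occurrences whose members are all correct and all inside the censorship
#' bounds; error rates divide unique erroneous member trials by member
#' observations counted with multiplicity.
#' @name scan
NULL

check_stream <- function(stream) {
  needed <- c("participant", "trial", "stimulus", "response", "correct", "rt_ms")
  missing_cols <- setdiff(needed, names(stream))
  if (length(missing_cols)) {
    stop("trial stream is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- !stream$stimulus %in% c("R", "L") | !stream$response %in% c("R", "L")
  if (any(bad)) {
    stop("stimulus/response codes must be 'R' or 'L' (rows ",
         paste(utils::head(which(bad), 5L), collapse = ", "), ")", call. = FALSE)
  }
  invisible(stream)
}

check_single_participant <- function(stream) {
  check_stream(stream)
  if (length(unique(stream$participant)) > 1L) {
    stop("expected a single participant's stream", call. = FALSE)
  }
  if (nrow(stream) > 1L) {
    d <- diff(stream$trial)
    if (any(d != 1L)) {
      stop("trial indices must be consecutive and sorted within participant",
           call. = FALSE)
    }
  }
  invisible(stream)
}

#' Find all overlapping occurrences of a history in one stream
#'
#' Every length-`nchar(history)` window whose stimulus sequence equals the
#' history counts, overlapping windows included. Nothing is filtered here;
#' correctness and censorship flags are attached for downstream use.
#'
#' @param stream One participant's trial stream (columns `participant`,
#'   `trial`, `stimulus`, `response`, `correct`, `rt_ms`), sorted by trial.
#' @param history String over \{R, L\}.
#' @param bounds Censorship bounds in ms, `c(low, high)` (default 200-980).
#' @return A data.frame with one row per occurrence: `start` (row position of
#'   the window's first trial, 1-based), `all_correct`, `all_in_bounds`.
#' @examples
#' s <- data.frame(participant = 1, trial = 0:5, stimulus = "R",
#'                 response = "R", correct = 1L, rt_ms = 500)
#' nrow(find_occurrences(s, "RRR")) # 4
#' @export
find_occurrences <- function(stream, history, bounds = c(200, 980)) {
  check_single_participant(stream)
  if (length(history) != 1L || !is.character(history) || is.na(history) ||
      nchar(history) < 1L || grepl("[^RL]", history)) {
    stop("history must be a non-empty string over {R, L}", call. = FALSE)
  }
  len <- nchar(history)
  n <- nrow(stream)
  empty <- data.frame(start = integer(0), all_correct = logical(0),
                      all_in_bounds = logical(0))
  if (n < len) return(empty)
  pat <- strsplit(history, "")[[1]]
  starts_ok <- rep(TRUE, n - len + 1L)
  for (j in seq_len(len)) {
    starts_ok <- starts_ok & stream$stimulus[seq_len(n - len + 1L) + j - 1L] == pat[j]
  }
  starts <- which(starts_ok)
  if (!length(starts)) return(empty)
  correct <- as.logical(stream$correct)
  in_b <- stream$rt_ms >= bounds[1] & stream$rt_ms <= bounds[2]
  all_correct <- vapply(starts, function(s) all(correct[s:(s + len - 1L)]), logical(1))
  all_in_bounds <- vapply(starts, function(s) all(in_b[s:(s + len - 1L)]), logical(1))
  data.frame(start = starts, all_correct = all_correct, all_in_bounds = all_in_bounds)
}

#' Censored mean RT for a history
#'
#' Averages over occurrences whose members are all correct and all within the
#' censorship bounds. In `terminal` mode (the sequential-effects convention:
#' trial-n latency conditioned on its history) the averaged quantity is each
#' valid occurrence's final-member RT; in `all` mode every member RT is
#' pooled.
#'
#' @inheritParams find_occurrences
#' @param mode `"terminal"` (default) or `"all"`.
#' @return A list with `mean_rt` (NA when no occurrence survives the filters)
#'   and `n_valid` (surviving occurrence count).
#' @export
history_mean_rt <- function(stream, history, bounds = c(200, 980),
                            mode = c("terminal", "all")) {
  mode <- match.arg(mode)
  if (bounds[1] >= bounds[2]) stop("bounds must satisfy low < high", call. = FALSE)
  occ <- find_occurrences(stream, history, bounds)
  len <- nchar(history)
  valid <- occ$start[occ$all_correct & occ$all_in_bounds]
  if (!length(valid)) {
    return(list(mean_rt = NA_real_, n_valid = 0L))
  }
  rts <- if (mode == "terminal") {
    stream$rt_ms[valid + len - 1L]
  } else {
    stream$rt_ms[as.vector(outer(valid, seq_len(len) - 1L, `+`))]
  }
  list(mean_rt = mean(rts), n_valid = length(valid))
}

#' Unique-error rate for a history
#'
#' Member observations count each trial once per occurrence it belongs to
#' (`nchar(history) * n_occurrences`); unique errors count distinct erroneous
#' trials belonging to at least one occurrence. E.g. 185 length-5 occurrences
#' with 56 distinct erroneous members give 56 / 925 = 0.0605.
#'
#' @inheritParams find_occurrences
#' @return A list with `n_occurrences`, `member_obs`, `unique_errors`, and
#'   `error_rate` (NA when there is no occurrence).
#' @export
unique_error_rate <- function(stream, history, bounds = c(200, 980)) {
  occ <- find_occurrences(stream, history, bounds)
  len <- nchar(history)
  n_occ <- nrow(occ)
  if (!n_occ) {
    return(list(n_occurrences = 0L, member_obs = 0L, unique_errors = 0L,
                error_rate = NA_real_))
  }
  members <- unique(as.vector(outer(occ$start, seq_len(len) - 1L, `+`)))
  errs <- sum(!as.logical(stream$correct[members]))
  list(n_occurrences = n_occ, member_obs = len * n_occ,
       unique_errors = as.integer(errs), error_rate = errs / (len * n_occ))
}

#' Unit-normalize a participant's history means
#'
#' `(x - min) / (max - min)`: the fastest mean maps to 0, the slowest to 1.
#' Missing entries are preserved as missing.
#'
#' @param x Numeric vector (possibly with NAs) of per-history means.
#' @return The normalized vector.
#' @examples
#' unit_normalize(c(400, 500, 600)) # 0, 0.5, 1
#' @export
unit_normalize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) {
    stop("need at least 2 non-missing means to normalize", call. = FALSE)
  }
  rng <- range(x[ok])
  if (rng[1] == rng[2]) {
    stop("degenerate range: all non-missing means are equal", call. = FALSE)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

all_histories <- function(depth, leading = "R") {
  unlist(lapply(seq_len(depth), function(k) {
    if (k == 1L) return(leading)
    tails <- do.call(expand.grid, rep(list(c("R", "L")), k - 1L))
    paste0(leading, apply(tails, 1L, paste, collapse = ""))
  }))
}

scan_participant <- function(stream, histories, tree, bounds, mode) {
  rows <- lapply(histories, function(h) {
    leading <- substr(h, 1L, 1L)
    if (leading == "R") {
      r <- history_to_ratio(h)
      om <- as.double(r)
    } else {
      r <- l_leading_ratio(h)
      om <- history_omega(h, wrap_l_leading = TRUE)
    }
    occ <- unique_error_rate(stream, h, bounds)
    m <- history_mean_rt(stream, h, bounds, mode)
    data.frame(
      history = h, level = nchar(h), numerator = r$num, denominator = r$den,
      omega = om, n_occurrences = occ$n_occurrences, n_valid = m$n_valid,
      mean_rt = m$mean_rt, member_obs = occ$member_obs,
      unique_errors = occ$unique_errors, error_rate = occ$error_rate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  # normalize within each leading set (R-leading and L-leading separately)
  out$norm_mean <- NA_real_
  for (lead in unique(substr(out$history, 1L, 1L))) {
    sel <- substr(out$history, 1L, 1L) == lead
    out$norm_mean[sel] <- unit_normalize(out$mean_rt[sel])
  }
  out
}

#' Scan multi-participant streams into per-history statistics
#'
#' For every participant and every R-leading (and optionally L-leading)
#' history up to `depth`, computes occurrence counts, censored mean RTs,
#' within-participant unit-normalized means, and unique-error rates. The
#' grand table is the unweighted across-participant mean of the normalized
#' means and error rates; a participant missing a history is dropped from
#' that history's grand mean with a warning.
#'
#' @param streams Trial-stream data.frame covering one or more participants.
#' @param depth History depth (default 5).
#' @param bounds Censorship bounds in ms (default `c(200, 980)`).
#' @param mode RT aggregation mode, `"terminal"` (default) or `"all"`.
#' @param l_leading Also scan the L-leading histories? Default FALSE.
#' @return A list with `per_participant` (one row per participant x history)
#'   and `grand` (one row per history, columns `norm_mean`, `error_rate`,
#'   `n_participants` plus the tree fields).
#' @export
analyze_streams <- function(streams, depth = 5L, bounds = c(200, 980),
                            mode = c("terminal", "all"), l_leading = FALSE) {
  mode <- match.arg(mode)
  check_stream(streams)
  if (!nrow(streams)) stop("empty trial stream", call. = FALSE)
  histories <- all_histories(depth, "R")
  if (l_leading) histories <- c(histories, all_histories(depth, "L"))
  parts <- split(streams, streams$participant)
  per <- lapply(names(parts), function(p) {
    one <- parts[[p]]
    one <- one[order(one$trial), , drop = FALSE]
    if (nrow(one) < depth) {
      stop(sprintf("participant %s has fewer than %d trials", p, depth),
           call. = FALSE)
    }
    cbind(participant = p, scan_participant(one, histories, NULL, bounds, mode))
  })
  per <- do.call(rbind, per)

  grand_rows <- lapply(histories, function(h) {
    sub <- per[per$history == h, , drop = FALSE]
    nm <- sub$norm_mean
    er <- sub$error_rate
    if (anyNA(nm)) {
      warning(sprintf("history %s missing for participant(s) %s; omitted from grand mean",
                      h, paste(sub$participant[is.na(nm)], collapse = ", ")),
              call. = FALSE)
    }
    data.frame(
      history = h, level = sub$level[1], numerator = sub$numerator[1],
      denominator = sub$denominator[1], omega = sub$omega[1],
      n_occurrences = sum(sub$n_occurrences), n_valid = sum(sub$n_valid),
      mean_rt = mean(sub$mean_rt, na.rm = TRUE),
      norm_mean = mean(nm, na.rm = TRUE),
      member_obs = sum(sub$member_obs),
      unique_errors = sum(sub$unique_errors),
      error_rate = mean(er, na.rm = TRUE),
      n_participants = sum(!is.na(nm)),
      stringsAsFactors = FALSE
    )
  })
  grand <- do.call(rbind, grand_rows)
  list(per_participant = per, grand = grand)
}

#' Export per-history statistics as a tab-separated table
#'
#' @param stats A per-participant or grand table from [analyze_streams()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_history_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
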