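#' @title Inferential battery for staircase and Farey-tree predictions
#' @description
#' Pearson correlations are converted to coefficients of determination and
#' F ratios via F = r^2 * df2 / (1 - r^2) with df1 = 1, and p-values come
#' from the upper tail of the F distribution; no multiple-testing correction
#' is applied. Missing histories are deleted pairwise and the effective n is
#' used in the degrees of freedom.
#' @name farey-stats
NULL

correlation_report <- function(test, n, r, df2, notes = "") {
  r2 <- r^2
  f <- if (r2 >= 1) Inf else r2 * df2 / (1 - r2)
  p <- if (is.infinite(f)) 0 else stats::pf(f, 1, df2, lower.tail = FALSE)
  structure(
    list(test = test, n = n, r = r, r2 = r2, F = f, df1 = 1L, df2 = df2,
         p = p, notes = notes),
    class = "correlation_report"
  )
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("%s: n = %d, r = %.4f, r2 = %.4f, F(%d, %d) = %s, p = %.4g%s\n",
              x$test, x$n, x$r, x$r2, x$df1, x$df2,
              if (is.infinite(x$F)) "Inf" else sprintf("%.2f", x$F), x$p,
              if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.correlation_report <- function(x, ...) {
  data.frame(test = x$test, n = x$n, r = x$r, r2 = x$r2, F = x$F,
             df1 = x$df1, df2 = x$df2, p = x$p, notes = x$notes,
             stringsAsFactors = FALSE)
}

resolve_grand <- function(x, col) {
  if (is.data.frame(x)) {
    stats::setNames(x[[col]], x$history)
  } else if (!is.null(names(x))) {
    x
  } else {
    stop("supply a grand table from analyze_streams() or a history-named vector",
         call. = FALSE)
  }
}

#' Staircase correlation test
#'
#' Pearson correlation between the grand normalized per-history means and the
#' staircase rotation number p/q looked up at each history's drive value
#' Omega (nearest grid point). The staircase predicts the relative latency of
#' each history, so the correlation is invariant to the affine freedom of the
#' unit normalization.
#'
#' @param norm_means Grand table from [analyze_streams()] (uses `norm_mean`)
#'   or a history-named numeric vector.
#' @param staircase A [devils_staircase()] table covering all history Omegas.
#' @param tree Tree from [build_farey_tree()]; rebuilt at depth 5 if NULL.
#' @return A `correlation_report` (r, r2, F with df (1, n-2), p).
#' @export
staircase_test <- function(norm_means, staircase, tree = NULL) {
  if (is.null(tree)) tree <- build_farey_tree(5L)
  y <- resolve_grand(norm_means, "norm_mean")
  omega <- if (is.data.frame(norm_means) && "omega" %in% names(norm_means)) {
    stats::setNames(norm_means$omega, norm_means$history)[names(y)]
  } else {
    vapply(names(y), history_omega, double(1))
  }
  x <- staircase_lookup(staircase, omega)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  n <- sum(ok)
  r <- stats::cor(x[ok], y[ok])
  correlation_report("staircase", n, r, n - 2L,
                     notes = if (n < length(y)) sprintf("%d missing dropped", length(y) - n) else "")
}

#' Spearman test of error rates against the binary Farey ranking
#'
#' Within each tree level, error rates are ranked descending (average ranks
#' for ties) and paired with the level's magnitude-descending binary ranks.
#' Because levels have different sizes, both rank vectors are rescaled to
#' the unit interval within each level ((rank - 1) / (level size - 1))
#' before concatenation, so that a perfect within-level agreement gives
#' rho = 1 and a full within-level reversal gives rho = -1 exactly. The
#' single-node level 1 carries no rank information and drops out, which is
#' why one extra degree of freedom is subtracted: df2 = n - 3. The
#' `"global"` scheme, kept for sensitivity checks, ranks all histories
#' jointly with df2 = n - 2.
#'
#' @param error_rates Grand table from [analyze_streams()] (uses
#'   `error_rate`) or a history-named numeric vector.
#' @param tree Tree from [build_farey_tree()]; rebuilt at depth 5 if NULL.
#' @param scheme `"within_level"` (default) or `"global"`.
#' @return A `correlation_report`; `notes` records tie counts.
#' @export
spearman_farey_test <- function(error_rates, tree = NULL,
                                scheme = c("within_level", "global")) {
  scheme <- match.arg(scheme)
  if (is.null(tree)) tree <- build_farey_tree(5L)
  er <- resolve_grand(error_rates, "error_rate")
  idx <- match(names(er), tree$history)
  if (anyNA(idx)) stop("unknown history in error_rates", call. = FALSE)
  lev <- tree$level[idx]
  rank_in_level <- tree$binary_rank[idx] - (2L^(lev - 1L) - 1L)
  ok <- !is.na(er)
  if (sum(ok) < 4L) stop("fewer than 4 complete values", call. = FALSE)
  if (any(!ok)) {
    warning(sprintf("%d missing error rate(s) dropped pairwise", sum(!ok)),
            call. = FALSE)
  }
  er <- er[ok]
  lev <- lev[ok]
  rank_in_level <- rank_in_level[ok]
  n_ties <- 0L
  if (scheme == "within_level") {
    x <- numeric(0)
    y <- numeric(0)
    for (l in sort(unique(lev))) {
      sel <- lev == l
      m <- sum(sel)
      if (m < 2L) next # the level-1 singleton carries no rank information
      x <- c(x, (rank_in_level[sel] - 1) / (m - 1))
      y <- c(y, (rank(-er[sel], ties.method = "average") - 1) / (m - 1))
      n_ties <- n_ties + sum(duplicated(er[sel]))
    }
    if (length(x) < 3L) stop("too few rankable values", call. = FALSE)
    df2 <- length(er) - 3L
  } else {
    x <- rank(tree$binary_rank[idx][ok])
    y <- rank(-er, ties.method = "average")
    n_ties <- sum(duplicated(er))
    df2 <- length(er) - 2L
  }
  rho <- stats::cor(x, y)
  correlation_report(paste0("spearman_farey(", scheme, ")"), length(er), rho, df2,
                     notes = sprintf("%d tie(s)", n_ties))
}

#' Regression of error rates on ratio denominators
#'
#' Ordinary least squares of error rate on the Farey denominator: larger
#' denominators are less stable resonances and should attract more errors.
#'
#' @inheritParams spearman_farey_test
#' @return A list with `slope`, `intercept`, a `correlation_report`
#'   (df (1, n-2)), and `fitted` (data.frame of denominator, error rate,
#'   fitted value) for plotting/export.
#' @export
denominator_regression <- function(error_rates, tree = NULL) {
  if (is.null(tree)) tree <- build_farey_tree(5L)
  er <- resolve_grand(error_rates, "error_rate")
  idx <- match(names(er), tree$history)
  if (anyNA(idx)) stop("unknown history in error_rates", call. = FALSE)
  den <- tree$den[idx]
  ok <- !is.na(er)
  er <- er[ok]
  den <- den[ok]
  if (length(er) < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::var(den) == 0) stop("degenerate predictor variance", call. = FALSE)
  fit <- stats::lm(er ~ den)
  slope <- unname(stats::coef(fit)[2])
  r <- if (stats::var(er) == 0) 0 else stats::cor(den, er)
  rep <- correlation_report("denominator_regression", length(er), r, length(er) - 2L)
  list(slope = slope, intercept = unname(stats::coef(fit)[1]), report = rep,
       fitted = data.frame(denominator = den, error_rate = er,
                           fitted = unname(stats::fitted(fit))))
}

#' Paired contrast between two trial histories
#'
#' Paired t statistic on the per-participant difference of raw
#' (unnormalized) history means, reported as F = t^2 with df (1, n - 1),
#' together with each history's mean and SD across participants.
#'
#' @param a,b Numeric vectors of per-participant mean RTs for the two
#'   histories, aligned by participant (NAs dropped pairwise).
#' @return A list with `F`, `df1`, `df2`, `p`, `n`, and per-history
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`. A zero-variance nonzero difference
#'   yields `F = Inf`.
#' @export
paired_contrast <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 2L) stop("fewer than 2 complete pairs", call. = FALSE)
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    f <- if (mean(d) == 0) 0 else Inf
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    f <- t_stat^2
  }
  p <- if (is.infinite(f)) 0 else stats::pf(f, 1, n - 1L, lower.tail = FALSE)
  list(F = f, df1 = 1L, df2 = n - 1L, p = p, n = n,
       mean_a = mean(a), sd_a = stats::sd(a),
       mean_b = mean(b), sd_b = stats::sd(b))
}

#' Partial r-squared decomposition of two predictors
#'
#' Full-model r^2 from the two-predictor least squares fit, plus each
#' predictor's squared partial correlation computed by residualizing both
#' the response and the predictor on the other predictor. Used to ask how
#' much variance the staircase captures beyond the bifurcation surface's
#' circular means, and vice versa.
#'
#' @param response Numeric response (e.g. 31 normalized means).
#' @param predictor1,predictor2 Numeric predictors (e.g. staircase p/q and
#'   bifurcation circular means).
#' @return A list with `r2_full`, `partial_r2_1`, `partial_r2_2`, `n`.
#'   Warns when the predictors are nearly collinear (|r| > 0.999).
#' @export
partial_r2 <- function(response, predictor1, predictor2) {
  ok <- stats::complete.cases(response, predictor1, predictor2)
  y <- response[ok]
  x1 <- predictor1[ok]
  x2 <- predictor2[ok]
  if (length(y) < 4L) stop("fewer than 4 complete triples", call. = FALSE)
  if (abs(stats::cor(x1, x2)) > 0.999) {
    warning("predictors are nearly collinear (|r| > 0.999)", call. = FALSE)
  }
  full <- stats::lm(y ~ x1 + x2)
  r2_full <- summary(full)$r.squared
  pr2 <- function(target, other) {
    ry <- stats::residuals(stats::lm(y ~ other))
    rx <- stats::residuals(stats::lm(target ~ other))
    stats::cor(ry, rx)^2
  }
  list(r2_full = r2_full, partial_r2_1 = pr2(x1, x2),
       partial_r2_2 = pr2(x2, x1), n = length(y))
}

#' Export correlation reports as a tab-separated table
#'
#' @param reports A list of `correlation_report` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  out <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
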