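test_that("overlap counting matches the repeated-letter worked example", {
  s <- homogeneous_stream(6) # RRRRRR, all correct
  counts <- vapply(c("R", "RR", "RRR", "RRRR", "RRRRR"),
                   function(h) nrow(find_occurrences(s, h)), integer(1))
  expect_equal(unname(counts), c(6L, 5L, 4L, 3L, 2L))
  # j repeated letters in m identical correct letters: m - j + 1 occurrences
  for (m in c(7L, 12L)) {
    sm <- homogeneous_stream(m)
    for (j in 1:5) {
      expect_equal(nrow(find_occurrences(sm, strrep("R", j))), m - j + 1L)
    }
  }
  expect_equal(nrow(find_occurrences(homogeneous_stream(2), "RRR")), 0L)
})

test_that("window counts are conserved across all patterns of a given length", {
  set.seed(4)
  s <- make_stream(sample(c("R", "L"), 200, replace = TRUE))
  for (k in c(2L, 3L)) {
    pats <- apply(do.call(expand.grid, rep(list(c("R", "L")), k)), 1, paste,
                  collapse = "")
    total <- sum(vapply(pats, function(h) nrow(find_occurrences(s, h)),
                        integer(1)))
    expect_equal(total, 200L - k + 1L)
    # R-leading patterns cover exactly the windows that start on an R
    r_total <- sum(vapply(pats[substr(pats, 1, 1) == "R"],
                          function(h) nrow(find_occurrences(s, h)), integer(1)))
    expect_equal(r_total, sum(s$stimulus[1:(200 - k + 1)] == "R"))
  }
  gappy <- make_stream(c("R", "L", "R"))
  gappy$trial <- c(0L, 2L, 3L)
  expect_error(find_occurrences(gappy, "R"), "consecutive")
})

test_that("unique-error rates divide distinct erroneous members by member observations", {
  # 185 disjoint RLLLL blocks; flip the first member of the first 56 blocks
  stim <- rep(c("R", "L", "L", "L", "L"), 185)
  resp <- stim
  errs <- (0:55) * 5 + 1
  resp[errs] <- "L"
  s <- make_stream(stim, resp)
  u <- unique_error_rate(s, "RLLLL")
  expect_equal(u$n_occurrences, 185L)
  expect_equal(u$member_obs, 925L)
  expect_equal(u$unique_errors, 56L)
  expect_equal(round(u$error_rate, 4), 0.0605)

  # an error shared by overlapping occurrences is counted once
  s2 <- make_stream(c("R", "R", "R"), c("R", "L", "R"))
  u2 <- unique_error_rate(s2, "RR") # occurrences at 1 and 2 share the error
  expect_equal(u2$n_occurrences, 2L)
  expect_equal(u2$unique_errors, 1L)
  expect_equal(u2$error_rate, 1 / 4)

  expect_equal(unique_error_rate(homogeneous_stream(10), "RRR")$error_rate, 0)
  one <- make_stream(c("R", "L", "L", "L", "L"), c("R", "R", "L", "L", "L"))
  expect_equal(unique_error_rate(one, "RLLLL")$error_rate, 0.2)
  none <- unique_error_rate(homogeneous_stream(3), "RRRRR")
  expect_true(is.na(none$error_rate))
  expect_true(u$unique_errors <= u$member_obs && u$error_rate <= 1)
})

test_that("history means honor correctness and censorship filters", {
  stim <- rep(c("R", "R", "R", "L"), 3)
  s <- make_stream(stim)
  s$rt_ms <- rep(c(400, 450, 500, 600), 3)
  s$rt_ms[c(3, 7, 11)] <- c(400, 500, 600) # terminal RTs of the RRR windows
  m <- history_mean_rt(s, "RRR")
  expect_equal(m$mean_rt, 500)
  expect_equal(m$n_valid, 3L)
  # an occurrence containing one error is excluded
  s_err <- s
  s_err$response[2] <- "L"
  s_err$correct[2] <- 0L
  expect_equal(history_mean_rt(s_err, "RRR")$n_valid, 2L)
  # an occurrence with one member beyond the bounds is excluded entirely
  s_cen <- s
  s_cen$rt_ms[2] <- 1500
  expect_equal(history_mean_rt(s_cen, "RRR")$n_valid, 2L)
  # widening bounds never decreases the valid count
  expect_gte(history_mean_rt(s_cen, "RRR", bounds = c(100, 2000))$n_valid,
             history_mean_rt(s_cen, "RRR")$n_valid)
  # "all members" mode pools every member RT
  m_all <- history_mean_rt(s, "RRR", mode = "all")
  expect_equal(m_all$mean_rt, mean(c(400, 450, 400, 400, 450, 500, 400, 450, 600)))
  # no valid occurrence is a flagged missing value, not zero
  nv <- history_mean_rt(make_stream("L"), "RRR")
  expect_true(is.na(nv$mean_rt))
  expect_error(history_mean_rt(s, "RRR", bounds = c(980, 200)), "low < high")
})

test_that("unit normalization is affine-invariant, idempotent, and NA-preserving", {
  expect_equal(unit_normalize(c(400, 500, 600)), c(0, 0.5, 1))
  x <- c(312, 480, NA, 401, 377)
  expect_equal(unit_normalize(3 * x + 17), unit_normalize(x))
  expect_equal(unit_normalize(unit_normalize(x)), unit_normalize(x))
  expect_true(is.na(unit_normalize(x)[3]))
  expect_error(unit_normalize(c(500, 500, 500)), "degenerate")
  expect_error(unit_normalize(c(500, NA)), "at least 2")
})

test_that("analyze_streams aggregates per participant and across participants", {
  s <- homogeneous_stream(6)
  s$rt_ms <- c(400, 420, 440, 460, 480, 500)
  res <- suppressWarnings(analyze_streams(s, depth = 5))
  g <- res$grand
  expect_equal(g$n_occurrences[g$history == "R"], 6L)
  expect_equal(g$n_occurrences[g$history == "RR"], 5L)
  expect_equal(g$n_occurrences[g$history == "RRRRR"], 2L)
  expect_equal(nrow(g), 31L)
  # two identical participants: grand means equal each participant's values
  s2 <- rbind(s, transform(s, participant = 2L))
  res2 <- suppressWarnings(analyze_streams(s2, depth = 5))
  p1 <- res2$per_participant[res2$per_participant$participant == "1", ]
  rr <- res2$grand$norm_mean[match(p1$history, res2$grand$history)]
  expect_equal(rr, p1$norm_mean)
  expect_error(analyze_streams(s[0, ]), "empty")
})

test_that("L-leading scanning adds the dual histories with wrapped drives", {
  set.seed(6)
  s <- make_stream(sample(c("R", "L"), 400, replace = TRUE),
                   rt = runif(400, 300, 700))
  res <- suppressWarnings(analyze_streams(s, depth = 3, l_leading = TRUE))
  g <- res$grand
  expect_equal(nrow(g), 14L) # 7 R-leading + 7 L-leading at depth 3
  expect_equal(g$omega[g$history == "LL"], 1) # 3/1 wrapped, 0 -> 1
  expect_equal(g$omega[g$history == "LR"], 0.5) # 3/2 wrapped
  expect_equal(g$denominator[g$history == "LL"], 1L)
})
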