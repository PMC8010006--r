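# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Default-parameter staircase on the full 0.001 grid (fast: vectorized map).
fs_staircase <- function() {
  if (is.null(.fixture_env$staircase)) {
    .fixture_env$staircase <- devils_staircase(seed = 42)
  }
  .fixture_env$staircase
}

fs_tree <- function() {
  if (is.null(.fixture_env$tree)) {
    .fixture_env$tree <- build_farey_tree(5L)
  }
  .fixture_env$tree
}

# A stream of identical correct trials, for the overlap-counting contracts.
homogeneous_stream <- function(n, stimulus = "R", rt = 500) {
  data.frame(participant = 1L, trial = seq_len(n) - 1L, stimulus = stimulus,
             response = stimulus, correct = 1L, rt_ms = rt,
             stringsAsFactors = FALSE)
}

# Build a stream from explicit stimulus/response vectors.
make_stream <- function(stimulus, response = stimulus, rt = 500,
                        participant = 1L) {
  data.frame(participant = participant, trial = seq_along(stimulus) - 1L,
             stimulus = stimulus, response = response,
             correct = as.integer(stimulus == response),
             rt_ms = rep_len(rt, length(stimulus)), stringsAsFactors = FALSE)
}
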