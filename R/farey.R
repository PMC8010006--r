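#' @title Farey-tree machinery for trial histories
#' @description
#' Every R-leading trial history (a string over \{R, L\} beginning with R,
#' oldest trial first) names a node of the mode-locking Farey tree grown from
#' the seed ratios 0/1 and 1/1. The node's mediant fraction is the resonance
#' ratio two coupled oscillators occupy when driven by that history, its
#' decimal value is the drive Omega fed to the circle map, and its binary
#' rank (level-ascending, magnitude-descending) spells the history itself in
#' binary (1 = R, 0 = L). L-leading histories live on the right half of the
#' Stern-Brocot tree and are reached by letter-swap duality: swap R and L,
#' resolve the R-leading ratio, take the reciprocal.
#' @name farey
NULL

gcd2 <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' Reduced ratio constructor
#'
#' Stores a fraction as an exact, reduced integer pair. Decimals are derived
#' views; no floating point enters the tree arithmetic.
#'
#' @param num Non-negative integer numerator.
#' @param den Positive integer denominator.
#' @return An object of class `farey_ratio`: a list with integer fields
#'   `num` and `den`, coprime.
#' @examples
#' farey_ratio(2, 7)
#' @export
farey_ratio <- function(num, den) {
  if (length(num) != 1L || length(den) != 1L ||
      !is.finite(num) || !is.finite(den) ||
      num != round(num) || den != round(den) || num < 0 || den <= 0) {
    stop("farey_ratio() needs a non-negative integer numerator and a positive integer denominator",
         call. = FALSE)
  }
  num <- as.integer(num)
  den <- as.integer(den)
  g <- if (num == 0L) den else gcd2(num, den)
  structure(list(num = num %/% g, den = den %/% g), class = "farey_ratio")
}

#' @export
print.farey_ratio <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.farey_ratio <- function(x, ...) paste0(x$num, "/", x$den)

#' Decimal value of a ratio
#' @param x A `farey_ratio`.
#' @param ... Unused.
#' @return `num/den` as a double.
#' @export
as.double.farey_ratio <- function(x, ...) x$num / x$den

#' Mediant of two ordered ratios
#'
#' The Farey tree's generating operation: numerators and denominators are
#' summed separately. The mediant always lies strictly between its parents.
#'
#' @param a,b `farey_ratio` objects with `a < b`.
#' @return The reduced mediant as a `farey_ratio`.
#' @examples
#' mediant(farey_ratio(0, 1), farey_ratio(1, 1)) # 1/2
#' mediant(farey_ratio(1, 2), farey_ratio(1, 1)) # 2/3
#' @export
mediant <- function(a, b) {
  stopifnot(inherits(a, "farey_ratio"), inherits(b, "farey_ratio"))
  if (a$num * b$den >= b$num * a$den) {
    stop("mediant() requires a < b", call. = FALSE)
  }
  farey_ratio(a$num + b$num, a$den + b$den)
}

#' Build the R-leading Farey tree
#'
#' Grows the tree from the seeds 0/1 and 1/1. The root (history "R") is their
#' mediant 1/2. From a node with bracketing parents (lo, hi) and value v,
#' appending a more recent R descends to mediant(lo, v) and appending L to
#' mediant(v, hi), so histories spell root-to-node paths, oldest trial first.
#' Binary ranks are assigned by sorting ascending by level and descending by
#' ratio magnitude within each level; the rank's binary digits reproduce the
#' history under 1 -> R, 0 -> L.
#'
#' @param depth Number of levels (default 5, giving the 31 one- to five-trial
#'   histories).
#' @return A data.frame with one row per node and columns `level`, `history`,
#'   `num`, `den`, `omega` (= num/den), `binary_rank`, and the bracketing
#'   parent ratios `lo_num`, `lo_den`, `hi_num`, `hi_den`, ordered by
#'   `binary_rank`.
#' @examples
#' tree <- build_farey_tree(5)
#' nrow(tree) # 31
#' subset(tree, history == "RRRL") # 2/7, rank 14
#' @export
build_farey_tree <- function(depth = 5L) {
  if (length(depth) != 1L || !is.finite(depth) || depth < 1) {
    stop("depth must be a positive integer", call. = FALSE)
  }
  depth <- as.integer(depth)
  n_nodes <- 2L^depth - 1L
  level <- integer(n_nodes)
  history <- character(n_nodes)
  num <- integer(n_nodes)
  den <- integer(n_nodes)
  lo_num <- integer(n_nodes)
  lo_den <- integer(n_nodes)
  hi_num <- integer(n_nodes)
  hi_den <- integer(n_nodes)

  # breadth-first fill; node i has children 2i (append R) and 2i+1 (append L)
  # in a heap layout, which mirrors the binary-rank digit structure
  fill <- function(i, h, lo, hi) {
    v <- mediant(lo, hi)
    level[i] <<- nchar(h)
    history[i] <<- h
    num[i] <<- v$num
    den[i] <<- v$den
    lo_num[i] <<- lo$num
    lo_den[i] <<- lo$den
    hi_num[i] <<- hi$num
    hi_den[i] <<- hi$den
    if (nchar(h) < depth) {
      fill(2L * i, paste0(h, "R"), lo, v)
      fill(2L * i + 1L, paste0(h, "L"), v, hi)
    }
  }
  fill(1L, "R", farey_ratio(0, 1), farey_ratio(1, 1))

  tree <- data.frame(
    level = level, history = history, num = num, den = den,
    omega = num / den,
    lo_num = lo_num, lo_den = lo_den, hi_num = hi_num, hi_den = hi_den,
    stringsAsFactors = FALSE
  )
  # rank: ascending by level, then descending by magnitude within level
  ord <- order(tree$level, -tree$omega)
  tree$binary_rank <- NA_integer_
  tree$binary_rank[ord] <- seq_len(n_nodes)
  tree[order(tree$binary_rank), , drop = FALSE]
}

validate_history <- function(history, leading = c("R", "L")) {
  leading <- match.arg(leading)
  if (length(history) != 1L || !is.character(history) || is.na(history) ||
      nchar(history) < 1L || grepl("[^RL]", history)) {
    stop("history must be a non-empty string over {R, L}", call. = FALSE)
  }
  first <- substr(history, 1L, 1L)
  if (first != leading) {
    stop(sprintf("expected a %s-leading history, got '%s'%s", leading, history,
                 if (leading == "R" && first == "L")
                   " (use l_leading_ratio() for L-leading histories)" else ""),
         call. = FALSE)
  }
  invisible(history)
}

#' Resolve an R-leading history to its mediant fraction
#'
#' Walks the Farey tree along the history's path: each R steps toward the
#' lower bracketing parent, each L toward the upper (e.g. R, RR, RRR, RRRL
#' visits 1/2, 1/3, 1/4, 2/7).
#'
#' @param history R-leading string over \{R, L\}, oldest trial first.
#' @return A `farey_ratio`.
#' @examples
#' history_to_ratio("RRRL")  # 2/7
#' history_to_ratio("RLRLR") # 8/13
#' @export
history_to_ratio <- function(history) {
  validate_history(history, "R")
  lo <- farey_ratio(0, 1)
  hi <- farey_ratio(1, 1)
  v <- mediant(lo, hi)
  letters_vec <- strsplit(history, "")[[1]]
  for (ch in letters_vec[-1]) {
    if (ch == "R") hi <- v else lo <- v
    v <- mediant(lo, hi)
  }
  v
}

#' Binary rank of a tree node
#'
#' The rank under the ordering "ascending by level, then descending by
#' magnitude within each level", starting at 1. The rank's binary digits
#' spell the node's history (1 -> R, 0 -> L), which is the arithmetic
#' verification route for the symbolic addresses.
#'
#' @param x Either an R-leading history string or a `farey_ratio` belonging
#'   to the tree.
#' @param tree A tree from [build_farey_tree()]; rebuilt at depth 5 if omitted.
#' @return Integer rank.
#' @examples
#' binary_rank("RRRL")            # 14
#' binary_rank(farey_ratio(8, 13)) # 21
#' @export
binary_rank <- function(x, tree = NULL) {
  if (is.null(tree)) tree <- build_farey_tree(5L)
  if (inherits(x, "farey_ratio")) {
    hit <- tree$num == x$num & tree$den == x$den
  } else {
    validate_history(x, "R")
    hit <- tree$history == x
  }
  if (!any(hit)) {
    stop("ratio/history is not a member of the tree", call. = FALSE)
  }
  tree$binary_rank[hit]
}

#' Inverse of [binary_rank()]: read a history off a rank's binary digits
#'
#' @param rank Positive integer.
#' @return The history spelled by the rank's binary representation under
#'   1 -> R, 0 -> L (most significant digit first, always R).
#' @examples
#' rank_to_history(14) # "RRRL"
#' rank_to_history(21) # "RLRLR"
#' @export
rank_to_history <- function(rank) {
  if (length(rank) != 1L || !is.finite(rank) || rank < 1 || rank != round(rank)) {
    stop("rank must be a positive integer", call. = FALSE)
  }
  rank <- as.integer(rank)
  digits <- character(0)
  while (rank > 0L) {
    digits <- c(if (rank %% 2L == 1L) "R" else "L", digits)
    rank <- rank %/% 2L
  }
  paste(digits, collapse = "")
}

#' L-leading ratio by Stern-Brocot duality
#'
#' The L-leading half of the Stern-Brocot tree mirrors the R-leading Farey
#' tree: an L-leading history's ratio is the reciprocal of its letter-swapped
#' R-leading complement (e.g. LL -> RR -> 1/3 -> 3/1).
#'
#' @param history L-leading string over \{R, L\}.
#' @return A `farey_ratio` with value > 1.
#' @examples
#' l_leading_ratio("LL")    # 3/1
#' l_leading_ratio("LRRRR") # 6/5
#' @export
l_leading_ratio <- function(history) {
  validate_history(history, "L")
  swapped <- chartr("RL", "LR", history)
  r <- history_to_ratio(swapped)
  farey_ratio(r$den, r$num)
}

#' Driving ratio Omega for a trial history
#'
#' The decimal value of the history's (Stern-Brocot) ratio. L-leading values
#' exceed 1; because the map's dynamics repeat for each integer increase in
#' Omega, they are by default wrapped modulo 1, with an exact 0 reported as 1.
#'
#' @param history R- or L-leading string over \{R, L\}.
#' @param wrap_l_leading Wrap L-leading values into (0, 1]? Default TRUE.
#' @return The drive value as a double.
#' @examples
#' history_omega("RRRL")   # 2/7 = 0.2857...
#' history_omega("LLLLL")  # 6/1 wrapped: 1
#' @export
history_omega <- function(history, wrap_l_leading = TRUE) {
  if (length(history) != 1L || !is.character(history) || is.na(history) ||
      nchar(history) < 1L || grepl("[^RL]", history)) {
    stop("history must be a non-empty string over {R, L}", call. = FALSE)
  }
  if (substr(history, 1L, 1L) == "R") {
    return(as.double(history_to_ratio(history)))
  }
  v <- as.double(l_leading_ratio(history))
  if (!wrap_l_leading) return(v)
  w <- v %% 1
  if (w == 0) 1 else w
}

#' The golden-ratio (strict alternation) path
#'
#' The branch R, RL, RLR, RLRL, RLRLR whose ratios are successive Fibonacci
#' quotients 1/2, 2/3, 3/5, 5/8, 8/13 converging to the golden ratio; it is
#' the tree's image of antiphase coordination.
#'
#' @param depth Path length (<= tree depth).
#' @return A data.frame with columns `history`, `num`, `den`, `omega`.
#' @examples
#' golden_path(5)
#' @export
golden_path <- function(depth = 5L) {
  if (length(depth) != 1L || !is.finite(depth) || depth < 1) {
    stop("depth must be a positive integer", call. = FALSE)
  }
  depth <- as.integer(depth)
  histories <- vapply(seq_len(depth), function(k) {
    paste(rep_len(c("R", "L"), k), collapse = "")
  }, character(1))
  ratios <- lapply(histories, history_to_ratio)
  data.frame(
    history = histories,
    num = vapply(ratios, function(r) r$num, integer(1)),
    den = vapply(ratios, function(r) r$den, integer(1)),
    omega = vapply(ratios, as.double, double(1)),
    stringsAsFactors = FALSE
  )
}

#' Export a Farey tree as a tab-separated table
#'
#' @param tree A tree from [build_farey_tree()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_farey_tree <- function(tree, path) {
  out <- tree[, c("level", "history", "num", "den", "omega", "binary_rank")]
  names(out)[names(out) == "num"] <- "numerator"
  names(out)[names(out) == "den"] <- "denominator"
  out$omega <- sprintf("%.6f", out$omega)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
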