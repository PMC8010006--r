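#' @title Discretized HKB circle map
#' @description
#' The two response fingers are modeled as coupled oscillators whose relative
#' phase phi (on the unit interval) obeys the discretized Haken-Kelso-Bunz
#' map
#' \deqn{\phi_{n+1} = \phi_n + \Omega - \frac{K}{2\pi}\,
#'   (1 + A\cos 2\pi\phi_n)\,\sin 2\pi\phi_n \quad (\mathrm{mod}\ 1),}
#' where Omega is the driving ratio (here, the decimal Farey ratio of a trial
#' history), K >= 0 the coupling strength, and A in [0, 1] the relative
#' prominence of the antiphase attractor. Since the coupling term equals
#' \eqn{\sin 2\pi\phi + (A/2)\sin 4\pi\phi} it is the standard two-attractor
#' HKB gradient. Note that at the defaults K = 0.95, A = 0.85 the map is
#' non-invertible (the coupling slope reaches K(1+A) > 1), so the dynamics
#' are chaotic in tongue-overlap windows; see the methods vignette.
#' @name circle-map
NULL

check_map_params <- function(omega, K, A) {
  if (!is.numeric(omega) || any(!is.finite(omega)) || any(omega < 0)) {
    stop("omega must be finite and >= 0", call. = FALSE)
  }
  if (length(K) != 1L || !is.finite(K) || K < 0) {
    stop("coupling K must be a single finite value >= 0", call. = FALSE)
  }
  if (length(A) != 1L || !is.finite(A) || A < 0 || A > 1) {
    stop("antiphase weight A must lie in [0, 1]", call. = FALSE)
  }
  invisible(NULL)
}

#' One step of the phase-attractive map
#'
#' Vectorized over `phi` (and `omega`, recycled).
#'
#' @param phi Current relative phase(s); in `[0, 1)` when `wrap = TRUE`.
#' @param omega Driving ratio(s), >= 0.
#' @param K Coupling strength (default 0.95).
#' @param A Antiphase attractor weight in `[0, 1]` (default 0.85).
#' @param wrap Reduce the result modulo 1? Default TRUE.
#' @return The next phase(s).
#' @examples
#' step_phase(0, omega = 0.3)    # coupling vanishes at phi = 0
#' step_phase(0.5, omega = 0.25) # and at phi = 1/2
#' @export
step_phase <- function(phi, omega, K = 0.95, A = 0.85, wrap = TRUE) {
  if (!is.numeric(phi) || any(!is.finite(phi))) {
    stop("phi must be finite", call. = FALSE)
  }
  check_map_params(omega, K, A)
  out <- phi + omega - (K / (2 * pi)) * (1 + A * cos(2 * pi * phi)) * sin(2 * pi * phi)
  if (wrap) out %% 1 else out
}

#' Iterate the map from a seed phase
#'
#' @param phi0 Seed phase.
#' @param omega,K,A Map parameters as in [step_phase()].
#' @param n Number of iterations (>= 0).
#' @param wrap Wrapped (`[0, 1)`) or unwrapped (accumulating) trajectory.
#' @return Numeric vector of length `n + 1`: `phi0` followed by the iterates.
#' @examples
#' iterate_map(0, omega = 0.1, K = 0, n = 10, wrap = FALSE) # pure rotation
#' @export
iterate_map <- function(phi0, omega, K = 0.95, A = 0.85, n, wrap = TRUE) {
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != round(n)) {
    stop("n must be a non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  out <- numeric(n + 1L)
  out[1L] <- if (wrap) phi0 %% 1 else phi0
  phi <- out[1L]
  for (i in seq_len(n)) {
    phi <- step_phase(phi, omega, K, A, wrap = wrap)
    out[i + 1L] <- phi
  }
  out
}

#' Rotation number (average rotations per iteration)
#'
#' Seeds the phase uniformly on the unit interval, iterates the map with the
#' modulus-1 operator disabled, and averages the per-iteration phase advance
#' over the final `n_avg` steps, i.e. `(phi_N - phi_(N - n_avg)) / n_avg`.
#' The first `n_iter - n_avg` iterations serve as the transient burn-in.
#'
#' @param omega Driving ratio(s); vectorized.
#' @param K,A Map parameters.
#' @param n_iter Total iterations (default 10000).
#' @param n_avg Averaged tail length (default 2500, must be <= `n_iter`).
#' @param phi0 Optional seed phase(s); drawn from the current RNG if NULL.
#' @return Estimated rotation number(s) rho, one per `omega`.
#' @examples
#' rotation_number(0.3, K = 0) # uncoupled limit: exactly omega
#' @export
rotation_number <- function(omega, K = 0.95, A = 0.85, n_iter = 10000L,
                            n_avg = 2500L, phi0 = NULL) {
  check_map_params(omega, K, A)
  if (n_avg > n_iter) stop("n_avg must be <= n_iter", call. = FALSE)
  if (is.null(phi0)) phi0 <- stats::runif(length(omega))
  phi <- rep_len(phi0, length(omega))
  phi_mark <- phi
  for (i in seq_len(n_iter)) {
    phi <- step_phase(phi, omega, K, A, wrap = FALSE)
    if (i == n_iter - n_avg) phi_mark <- phi
  }
  (phi - phi_mark) / n_avg
}

#' Devil's staircase: rotation number across a drive grid
#'
#' One rotation-number estimate per grid point, each from its own
#' uniform-random seed phase drawn sequentially from the RNG, so a single
#' integer seed reproduces the whole staircase bit-for-bit.
#'
#' @param K,A Map parameters (defaults 0.95 and 0.85, the values that give
#'   wide Arnold tongues and a connected staircase).
#' @param omega Ascending grid of drive values (default 0 to 1 by 0.001).
#' @param n_iter,n_avg As in [rotation_number()].
#' @param seed Optional integer seed set before drawing the seed phases.
#' @return A data.frame of class `devils_staircase` with columns `omega` and
#'   `rho`, plus attributes `K`, `A`, `n_iter`, `n_avg`.
#' @examples
#' st <- devils_staircase(omega = seq(0, 1, by = 0.05), n_iter = 2000,
#'                        n_avg = 500, seed = 1)
#' @export
devils_staircase <- function(K = 0.95, A = 0.85, omega = seq(0, 1, by = 0.001),
                             n_iter = 10000L, n_avg = 2500L, seed = NULL) {
  if (length(omega) < 1L) stop("omega grid must be non-empty", call. = FALSE)
  if (is.unsorted(omega, strictly = FALSE)) {
    stop("omega grid must be sorted ascending", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  phi0 <- stats::runif(length(omega))
  rho <- rotation_number(omega, K = K, A = A, n_iter = n_iter, n_avg = n_avg,
                         phi0 = phi0)
  out <- data.frame(omega = omega, rho = rho)
  attr(out, "K") <- K
  attr(out, "A") <- A
  attr(out, "n_iter") <- n_iter
  attr(out, "n_avg") <- n_avg
  class(out) <- c("devils_staircase", "data.frame")
  out
}

#' Nearest-grid-point staircase lookup
#'
#' @param staircase A [devils_staircase()] table.
#' @param omega Drive value(s) to look up.
#' @return rho at the nearest grid point(s); with the default 0.001 grid the
#'   grid discrepancy is at most 0.0005 in omega.
#' @export
staircase_lookup <- function(staircase, omega) {
  if (!is.numeric(omega) || any(!is.finite(omega))) {
    stop("omega must be finite", call. = FALSE)
  }
  grid <- staircase$omega
  if (any(omega < grid[1] - 1e-9) || any(omega > grid[length(grid)] + 1e-9)) {
    stop("omega outside the staircase grid", call. = FALSE)
  }
  idx <- findInterval(omega, grid, all.inside = TRUE)
  # findInterval gives the left neighbor; move right when it is closer
  right_closer <- (grid[idx + 1L] - omega) < (omega - grid[idx])
  idx <- idx + as.integer(right_closer)
  staircase$rho[idx]
}

#' Bifurcation surface of retained wrapped phases
#'
#' For each of `n_omega` evenly spaced drive values on [0, 1], iterates a
#' wrapped trajectory from a uniform-random seed phase and retains the final
#' `n_keep` phases together with their circular mean. The retained phases
#' trace the map's phase-attractive regions.
#'
#' @param K,A Map parameters.
#' @param n_omega Number of drive values (default 1000).
#' @param n_iter Iterations per drive value (default 10000).
#' @param n_keep Retained final phases (default 100, must be <= `n_iter`).
#' @param seed Optional integer seed.
#' @return An object of class `bifurcation_surface`: a list with `omega`
#'   (length `n_omega`), `phases` (`n_omega` x `n_keep` matrix in `[0, 1)`),
#'   and `circular_mean` (length `n_omega`, values in `(0, 1]`).
#' @export
bifurcation_surface <- function(K = 0.95, A = 0.85, n_omega = 1000L,
                                n_iter = 10000L, n_keep = 100L, seed = NULL) {
  if (n_keep > n_iter) stop("n_keep must be <= n_iter", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  omega <- seq(0, 1, length.out = n_omega)
  phi <- stats::runif(n_omega)
  phases <- matrix(NA_real_, nrow = n_omega, ncol = n_keep)
  for (i in seq_len(n_iter)) {
    phi <- step_phase(phi, omega, K, A, wrap = TRUE)
    if (i > n_iter - n_keep) phases[, i - (n_iter - n_keep)] <- phi
  }
  cm <- apply(phases, 1L, function(p) {
    tryCatch(circular_mean(p), error = function(e) NA_real_)
  })
  structure(
    list(omega = omega, phases = phases, circular_mean = cm,
         K = K, A = A, n_iter = n_iter, n_keep = n_keep),
    class = "bifurcation_surface"
  )
}

#' @export
print.bifurcation_surface <- function(x, ...) {
  cat(sprintf("bifurcation surface: %d drive values, final %d phases each (K = %g, A = %g)\n",
              length(x$omega), x$n_keep, x$K, x$A))
  invisible(x)
}

#' @export
as.data.frame.bifurcation_surface <- function(x, ...) {
  n_keep <- ncol(x$phases)
  data.frame(
    omega = rep(x$omega, each = n_keep),
    phase_index = rep(seq_len(n_keep), times = length(x$omega)),
    phase = as.vector(t(x$phases)),
    circular_mean = rep(x$circular_mean, each = n_keep)
  )
}

#' Circular mean of wrapped phases
#'
#' The angle of the mean unit vector at angles `2 * pi * phase`, mapped back
#' to the unit interval. Respects the adjacency of 0 and 1; by convention an
#' exact 0 is reported as 1, so the result lies in (0, 1].
#'
#' @param phases Non-empty vector of wrapped phases in `[0, 1)`.
#' @return The circular mean in (0, 1].
#' @examples
#' circular_mean(c(0.1, 0.9)) # symmetric about 0 -> reported as 1
#' @export
circular_mean <- function(phases) {
  if (length(phases) == 0L || !is.numeric(phases) || any(!is.finite(phases))) {
    stop("phases must be a non-empty finite numeric vector", call. = FALSE)
  }
  s <- mean(sin(2 * pi * phases))
  c_ <- mean(cos(2 * pi * phases))
  if (sqrt(s^2 + c_^2) < 1e-12) {
    stop("circular mean undefined: zero resultant vector", call. = FALSE)
  }
  m <- (atan2(s, c_) / (2 * pi)) %% 1
  if (m == 0) 1 else m
}

#' Export a staircase as a tab-separated table
#'
#' @param staircase A [devils_staircase()] table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_staircase <- function(staircase, path) {
  out <- data.frame(omega = sprintf("%.6f", staircase$omega),
                    rho = sprintf("%.6f", staircase$rho))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a bifurcation surface as a tab-separated table
#'
#' Long format: one row per retained phase, columns
#' (omega, phase_index, phase, circular_mean).
#'
#' @param surface A [bifurcation_surface()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bifurcation <- function(surface, path) {
  out <- as.data.frame(surface)
  for (col in c("omega", "phase", "circular_mean")) {
    out[[col]] <- sprintf("%.6f", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
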