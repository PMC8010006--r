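test_that("single map steps match hand-computed values", {
  # coupling vanishes where sin(2*pi*phi) = 0
  expect_equal(step_phase(0, omega = 0.3), 0.3)
  expect_equal(step_phase(0.5, omega = 0.25), 0.75)
  # at phi = 1/4 the antiphase term dies (cos(pi/2) = 0): phi - K/(2*pi)
  expect_equal(step_phase(0.25, omega = 0, K = 0.95, A = 0.85),
               0.25 - 0.95 / (2 * pi), tolerance = 1e-12)
  expect_equal(step_phase(0.25, omega = 0, K = 0.95, A = 0.85), 0.09880280,
               tolerance = 1e-7)
  expect_error(step_phase(NaN, omega = 0.3), "finite")
  expect_error(step_phase(0.2, omega = -1), "omega")
  expect_error(step_phase(0.2, omega = 0.3, A = 2), "A")
})

test_that("iteration honors length, wrap, and the pure-rotation limit", {
  expect_equal(iterate_map(0.37, 0.5, n = 0), 0.37)
  traj <- iterate_map(0, omega = 0.1, K = 0, n = 10, wrap = FALSE)
  expect_equal(length(traj), 11L)
  expect_equal(traj[11], 1.0)
  wrapped <- iterate_map(0.37, omega = 0.5, K = 0.95, A = 0.85, n = 1000)
  expect_true(all(wrapped >= 0 & wrapped < 1))
  expect_error(iterate_map(0, 0.5, n = -1), "non-negative")
})

test_that("rotation number is exact in the uncoupled limit and on the 1/2 plateau", {
  set.seed(1)
  for (om in c(0.137, 0.3, 0.72)) {
    expect_equal(rotation_number(om, K = 0), om, tolerance = 1e-12)
  }
  # omega = 1/2 sits mid-plateau at the default parameters
  set.seed(2)
  expect_equal(rotation_number(0.5), 0.5, tolerance = 0.005)
  expect_error(rotation_number(0.5, n_iter = 100, n_avg = 200), "n_avg")
})

test_that("the staircase hits its endpoints and equals omega when uncoupled", {
  st <- devils_staircase(omega = c(0, 0.5, 1), n_iter = 5000, n_avg = 1000,
                         seed = 7)
  expect_equal(st$rho, c(0, 0.5, 1), tolerance = 0.005)
  grid <- seq(0, 1, by = 0.05)
  st0 <- devils_staircase(K = 0, omega = grid, n_iter = 2000, n_avg = 500,
                          seed = 7)
  expect_equal(st0$rho, grid, tolerance = 1e-12)
  expect_error(devils_staircase(omega = numeric(0)), "non-empty")
  expect_error(devils_staircase(omega = c(0.5, 0.1)), "ascending")
})

test_that("identical seeds give bit-identical staircases and surfaces", {
  a <- devils_staircase(omega = seq(0, 1, by = 0.02), n_iter = 2000,
                        n_avg = 500, seed = 123)
  b <- devils_staircase(omega = seq(0, 1, by = 0.02), n_iter = 2000,
                        n_avg = 500, seed = 123)
  expect_identical(a$rho, b$rho)
  s1 <- bifurcation_surface(n_omega = 50, n_iter = 1000, n_keep = 20, seed = 5)
  s2 <- bifurcation_surface(n_omega = 50, n_iter = 1000, n_keep = 20, seed = 5)
  expect_identical(s1$phases, s2$phases)
})

test_that("monotonicity, odd symmetry, and convergence hold for an invertible map", {
  # K(1 + A) < 1 keeps the map a homeomorphism, where the rotation number
  # is unique: the staircase must be non-decreasing and odd-symmetric, and
  # the estimator must be converged. (At the chaotic defaults these are
  # genuine dynamical violations, not estimator noise; see the vignette.)
  grid <- seq(0, 1, by = 0.01)
  st <- devils_staircase(K = 0.4, A = 0.85, omega = grid, n_iter = 4000,
                         n_avg = 1000, seed = 31)
  expect_true(all(diff(st$rho) >= -0.01))
  expect_true(max(abs(st$rho + rev(st$rho) - 1)) < 0.02)
  st2 <- devils_staircase(K = 0.4, A = 0.85, omega = grid, n_iter = 8000,
                          n_avg = 1000, seed = 31)
  expect_true(max(abs(st2$rho - st$rho)) < 0.005)
})

test_that("staircase lookup returns the nearest grid point", {
  st <- devils_staircase(K = 0, omega = seq(0, 1, by = 0.1), n_iter = 500,
                         n_avg = 100, seed = 3)
  expect_equal(staircase_lookup(st, 0.52), 0.5, tolerance = 1e-12)
  expect_equal(staircase_lookup(st, 0.58), 0.6, tolerance = 1e-12)
  expect_equal(staircase_lookup(st, c(0, 1)), c(0, 1), tolerance = 1e-12)
  expect_error(staircase_lookup(st, 1.2), "outside")
})

test_that("circular means respect the adjacency of 0 and 1", {
  expect_equal(circular_mean(0.25), 0.25)
  expect_equal(circular_mean(c(0.1, 0.9)), 1) # resultant at angle 0 -> 1
  expect_equal(circular_mean(c(0.2, 0.3, 0.4)), 0.3, tolerance = 1e-12)
  # independent vector-sum oracle on an asymmetric set
  ph <- c(0.05, 0.1, 0.85)
  ang <- atan2(sum(sin(2 * pi * ph)), sum(cos(2 * pi * ph))) / (2 * pi)
  expect_equal(circular_mean(ph), ang %% 1, tolerance = 1e-12)
  expect_error(circular_mean(numeric(0)), "non-empty")
  expect_error(circular_mean(c(0, 0.25, 0.5, 0.75)), "zero resultant")
})

test_that("bifurcation surfaces keep wrapped phases and show mode-locked contraction", {
  surf <- bifurcation_surface(n_omega = 21, n_iter = 3000, n_keep = 50,
                              seed = 9)
  expect_true(all(surf$phases >= 0 & surf$phases < 1))
  expect_equal(dim(surf$phases), c(21L, 50L))
  expect_error(bifurcation_surface(n_iter = 10, n_keep = 20), "n_keep")

  # mode-locked at omega = 1/2: the attractor is the 2-cycle {0, 1/2}, so
  # the retained phases collapse onto a couple of narrow bands
  n_bands <- function(p) length(unique(round(p, 3) %% 1))
  set.seed(10)
  locked <- tail(iterate_map(runif(1), 0.5, K = 0.95, A = 0.85, n = 3000), 100)
  expect_lte(n_bands(locked), 3L)
  expect_equal(sort(unique(round(locked, 3) %% 1)), c(0, 0.5), tolerance = 1e-3)
  # uncoupled irrational rotation equidistributes: resultant near 0, no bands
  golden <- (sqrt(5) - 1) / 2
  free <- tail(iterate_map(runif(1), golden, K = 0, n = 3000), 600)
  resultant <- function(p) sqrt(mean(sin(2 * pi * p))^2 + mean(cos(2 * pi * p))^2)
  expect_lt(resultant(free), 0.1)
  expect_gt(n_bands(free), 100L)
})
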