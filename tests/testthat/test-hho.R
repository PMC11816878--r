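test_that("escape energy follows E = 2 E0 (1 - t/T)", {
  expect_equal(escape_energy(0.7, 10, 10), 0)      # zero at t = T for any E0
  expect_equal(escape_energy(1, 0, 100), 2)        # starts at 2 with E0 = 1
  expect_equal(escape_energy(1, 50, 100), 1)
  expect_equal(escape_energy(-0.5, 25, 100), -0.75)
  expect_error(escape_energy(1, 5, 0), "t_max")
  expect_error(escape_energy(1, 11, 10), "`t`")
})

test_that("mean position equals the per-dimension arithmetic mean", {
  same <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(mean_position(same), c(1, 2, 3))
  expect_equal(mean_position(rbind(c(1, 3), c(3, 1))), c(2, 2))
  set.seed(2)
  P <- matrix(rnorm(50), 10, 5)
  acc <- numeric(5)
  for (i in 1:10) acc <- acc + P[i, ]   # brute-force accumulation
  expect_equal(mean_position(P), acc / 10)
  expect_error(mean_position(matrix(numeric(0), 0, 2)), "non-empty")
})

test_that("update rules reduce to their closed forms at fixed random draws", {
  # exploration, q >= 0.5 branch with r1 = 0 collapses to X_rand
  expect_equal(exploration_step(x = 3, x_rand = 7, x_rabbit = 0, x_mean = 0,
                                lb = -10, ub = 10, q = 0.9, r1 = 0, r2 = 0.3),
               7)
  # exploration, q < 0.5 branch with r3 = 0 collapses to X_rabbit - X_mean
  expect_equal(exploration_step(x = 3, x_rand = 7, x_rabbit = 5, x_mean = 2,
                                lb = -10, ub = 10, q = 0.1, r3 = 0, r4 = 0.8),
               3)
  # exploration, q < 0.5, r3 = 1, r4 = 0 -> X_rabbit - X_mean - LB
  expect_equal(exploration_step(x = 3, x_rand = 7, x_rabbit = 5, x_mean = 2,
                                lb = -10, ub = 10, q = 0.1, r3 = 1, r4 = 0),
               5 - 2 - (-10))
  # soft besiege scalar cases
  expect_equal(soft_besiege(3, 5, e = 0, j = 1.3), 2)
  expect_equal(soft_besiege(3, 5, e = 0.5, j = 1), 2 - 0.5 * abs(5 - 3))
  expect_equal(soft_besiege(4, 5, e = 1, j = 0), (5 - 4) - abs(4))
  # hard besiege scalar cases
  expect_equal(hard_besiege(3, 5, e = 0), 5)
  expect_equal(hard_besiege(3, 5, e = 0.2), 5 - 0.2 * 2)
  expect_equal(hard_besiege(5, 5, e = 0.77), 5)
  # rapid dive scalar cases
  expect_equal(rapid_dive_step(x_rabbit = 5, x_mean = 1, e = 0, j = 1), 5)
  expect_equal(rapid_dive_step(x_rabbit = 2, x_mean = 2 * 1.0, e = 0.9, j = 1), 2)
  expect_equal(rapid_dive_step(x_rabbit = 2, x_mean = 1, e = 1, j = 1), 1)
})

test_that("the optimizer is monotone, bounded, seeded, and budget-accounted", {
  sphere <- function(x) sum(x^2)
  seen <- new.env(); seen$bad <- 0L
  watched <- function(x) {
    if (any(x < -5 - 1e-12) || any(x > 5 + 1e-12)) seen$bad <- seen$bad + 1L
    sphere(x)
  }
  p <- hho_params(n_pop = 10, n_iter = 30, lb = -5, ub = 5, seed = 21)
  res <- hho_minimize(watched, dim = 4, params = p)
  expect_identical(seen$bad, 0L)                          # bound respect
  expect_true(all(diff(res$history$best_cost) <= 0))      # monotone best
  expect_equal(res$history$energy[nrow(res$history)], 0)  # E(t = T) = 0
  expect_true(all(abs(res$history$energy[-1]) <= 2))      # energy envelope
  expect_lte(res$n_evals, 10 * (30 * 2 + 1))              # budget ceiling
  res2 <- hho_minimize(watched, dim = 4, params = p)
  expect_identical(res$history, res2$history)             # seeded determinism
  expect_identical(res$best_position, res2$best_position)
})

test_that("fixed-E0 mode starts the energy schedule at 2", {
  sphere <- function(x) sum(x^2)
  p <- hho_params(n_pop = 5, n_iter = 10, lb = -1, ub = 1, seed = 3,
                  e0_mode = "fixed", e0_init = 1)
  res <- hho_minimize(sphere, dim = 2, params = p)
  e <- res$history$energy[-1]
  expect_equal(e, 2 * (1 - (1:10) / 10))
})

test_that("HHO beats equal-budget random search on the sphere", {
  sphere <- function(x) sum(x^2)
  hho_best <- rand_best <- numeric(5)
  for (s in 1:5) {
    res <- hho_minimize(sphere, dim = 5,
                        hho_params(n_pop = 15, n_iter = 40, lb = -10, ub = 10,
                                   seed = s))
    rs <- random_search_minimize(sphere, dim = 5, n_evals = res$n_evals,
                                 lb = -10, ub = 10, seed = s)
    hho_best[s] <- res$best_cost; rand_best[s] <- rs$best_cost
  }
  expect_lt(median(hho_best), 1e-2)
  expect_lt(median(hho_best), median(rand_best))
})

test_that("non-finite costs are rejected, not propagated", {
  trap <- function(x) if (x[1] > 0.5) NaN else sum(x^2)
  p <- hho_params(n_pop = 6, n_iter = 10, lb = 0, ub = 1, seed = 5)
  w <- capture_warnings(res <- hho_minimize(trap, dim = 2, params = p))
  expect_gt(length(w), 0)
  expect_true(all(grepl("non-finite", w)))
  expect_true(is.finite(res$best_cost))
  expect_lte(res$best_position[1], 0.5)
})

test_that("a T = 1 run returns the best seen after one sweep", {
  sphere <- function(x) sum(x^2)
  p <- hho_params(n_pop = 4, n_iter = 1, lb = -2, ub = 2, seed = 8)
  res <- hho_minimize(sphere, dim = 3, params = p)
  expect_identical(nrow(res$history), 2L)
  expect_lte(res$best_cost, res$history$best_cost[1])
  expect_equal(res$best_cost, sphere(res$best_position))
})

test_that("levy dives keep monotonicity and can only spend extra evaluations", {
  sphere <- function(x) sum(x^2)
  p <- hho_params(n_pop = 8, n_iter = 20, lb = -3, ub = 3, seed = 13,
                  levy_dives = TRUE)
  res <- hho_minimize(sphere, dim = 3, params = p)
  expect_true(all(diff(res$history$best_cost) <= 0))
  expect_true(is.finite(res$best_cost))
})
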