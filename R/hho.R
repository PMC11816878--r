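# Harris Hawks Optimization (HHO) as a general continuous minimizer.
#
# HHO mimics cooperative hawk hunting. A decaying "escape energy" E switches
# the population between exploration (|E| >= 1) and exploitation of the best
# solution found so far (the "rabbit"): soft besiege (|E| >= 0.5), hard
# besiege (|E| < 0.5), and greedy rapid dives.

#' Escape energy schedule
#'
#' `E = 2 * E0 * (1 - t / T)`: the energy envelope decays linearly from
#' `2 * E0` at t = 0 to exactly 0 at t = T.
#'
#' @param e0 Initial energy draw (original convention: U(-1, 1) per
#'   iteration).
#' @param t Current iteration, `0 <= t <= T`.
#' @param t_max Maximum iteration count T (>= 1).
#' @return The energy coefficient E.
#' @export
escape_energy <- function(e0, t, t_max) {
  check_number(e0, "e0")
  check_number(t_max, "t_max")
  if (t_max < 1) stop_arg("`t_max` must be >= 1")
  check_number(t, "t", lower = 0, upper = t_max)
  2 * e0 * (1 - t / t_max)
}

#' Centroid of a hawk population
#'
#' @param population Matrix with one hawk position per row.
#' @return Arithmetic mean per dimension.
#' @export
mean_position <- function(population) {
  if (!is.matrix(population) || nrow(population) == 0L) {
    stop_arg("`population` must be a non-empty matrix")
  }
  colMeans(population)
}

#' Exploration update (perching)
#'
#' With probability `q >= 0.5` the hawk perches relative to a random
#' population member: `X' = X_rand - r1 * |X_rand - 2 r2 X|`; otherwise it
#' perches relative to the prey and the population centroid:
#' `X' = (X_rabbit - X_mean) - r3 (LB + r4 (UB - LB))`. r1..r4, q ~ U(0, 1)
#' unless supplied.
#'
#' @param x Current position.
#' @param x_rand Position of a randomly chosen hawk.
#' @param x_rabbit Best position so far.
#' @param x_mean Population centroid.
#' @param lb,ub Per-dimension bounds.
#' @param q,r1,r2,r3,r4 Optional fixed random draws (for testing).
#' @return New position (not yet clamped).
#' @export
exploration_step <- function(x, x_rand, x_rabbit, x_mean, lb, ub,
                             q = stats::runif(1), r1 = stats::runif(1),
                             r2 = stats::runif(1), r3 = stats::runif(1),
                             r4 = stats::runif(1)) {
  if (q >= 0.5) {
    x_rand - r1 * abs(x_rand - 2 * r2 * x)
  } else {
    (x_rabbit - x_mean) - r3 * (lb + r4 * (ub - lb))
  }
}

#' Soft besiege update
#'
#' `X' = (X_rabbit - X) - E * |J * X_rabbit - X|`, the gradual convergence
#' move used when the prey still has energy (`|E| >= 0.5`).
#'
#' @param x Current position.
#' @param x_rabbit Best position so far.
#' @param e Escape energy.
#' @param j Escape step, random in `[0, 2]`.
#' @return New position.
#' @export
soft_besiege <- function(x, x_rabbit, e, j) {
  (x_rabbit - x) - e * abs(j * x_rabbit - x)
}

#' Hard besiege update
#'
#' `X' = X_rabbit - E * |X_rabbit - X|`, the direct dive used when the prey
#' is exhausted (`|E| < 0.5`).
#'
#' @inheritParams soft_besiege
#' @return New position.
#' @export
hard_besiege <- function(x, x_rabbit, e) {
  x_rabbit - e * abs(x_rabbit - x)
}

#' Rapid dive update
#'
#' `X' = X_rabbit - E * |J * X_rabbit - X_mean|`; in the optimizer this
#' candidate is accepted only if it improves on the hawk's current cost
#' (greedy acceptance).
#'
#' @param x_rabbit Best position so far.
#' @param x_mean Population centroid.
#' @param e Escape energy.
#' @param j Escape step in `[0, 2]`.
#' @return Candidate position.
#' @export
rapid_dive_step <- function(x_rabbit, x_mean, e, j) {
  x_rabbit - e * abs(j * x_rabbit - x_mean)
}

# Levy flight step (Mantegna), used only when levy_dives = TRUE.
levy_step <- function(dim, beta = 1.5) {
  num <- gamma(1 + beta) * sin(pi * beta / 2)
  den <- gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)
  sigma <- (num / den)^(1 / beta)
  u <- stats::rnorm(dim) * sigma
  v <- stats::rnorm(dim)
  u / abs(v)^(1 / beta)
}

#' HHO optimizer parameters
#'
#' @param n_pop Population size N (>= 2; default 30).
#' @param n_iter Iteration budget T (>= 1; default 100).
#' @param lb,ub Per-dimension bounds (scalars recycled; `lb < ub`).
#' @param seed RNG seed; runs are fully reproducible under it.
#' @param e0_mode `"resample"` draws E0 ~ U(-1, 1) each iteration (original
#'   convention, energy decays randomly from 2 toward 0); `"fixed"` keeps
#'   `E0 = e0_init` throughout.
#' @param e0_init Fixed initial energy scale used when `e0_mode = "fixed"`
#'   (default 1, so E starts at 2).
#' @param levy_dives Add the original Levy-flight progressive dive as a
#'   second greedy candidate (default FALSE: exactly the printed update
#'   rules).
#' @return A list of class `"hho_params"`.
#' @export
hho_params <- function(n_pop = 30L, n_iter = 100L, lb = 0, ub = 1,
                       seed = NULL, e0_mode = c("resample", "fixed"),
                       e0_init = 1, levy_dives = FALSE) {
  check_number(n_pop, "n_pop", lower = 2)
  check_number(n_iter, "n_iter", lower = 1)
  e0_mode <- match.arg(e0_mode)
  check_flag(levy_dives, "levy_dives")
  if (any(lb >= ub)) stop_arg("`lb` must be elementwise below `ub`")
  structure(list(n_pop = as.integer(n_pop), n_iter = as.integer(n_iter),
                 lb = lb, ub = ub, seed = seed, e0_mode = e0_mode,
                 e0_init = e0_init, levy_dives = levy_dives),
            class = "hho_params")
}

#' Minimize a cost function with Harris Hawks Optimization
#'
#' Per iteration the escape energy `E = 2 E0 (1 - t/T)` dispatches each hawk:
#' exploration when `|E| >= 1`; otherwise soft besiege (`r >= 0.5`,
#' `|E| >= 0.5`), hard besiege (`r >= 0.5`, `|E| < 0.5`), or a rapid dive
#' with greedy acceptance (`r < 0.5`). Positions are clamped to the bounds
#' before evaluation; non-finite costs reject the candidate with a warning.
#'
#' @param cost_fn Function mapping a position vector to a scalar cost.
#' @param dim Problem dimension.
#' @param params An [hho_params()].
#' @return List of class `"hho_result"`: `best_position`, `best_cost`,
#'   `history` (data frame: iteration, best_cost, mean_cost, energy),
#'   `n_evals`.
#' @export
hho_minimize <- function(cost_fn, dim, params = hho_params()) {
  if (!inherits(params, "hho_params")) stop_arg("`params` must be hho_params")
  check_number(dim, "dim", lower = 1)
  N <- params$n_pop; T_ <- params$n_iter
  lb <- rep_len(params$lb, dim); ub <- rep_len(params$ub, dim)
  n_evals <- 0L
  evaluate <- function(x) {
    n_evals <<- n_evals + 1L
    v <- cost_fn(x)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || !is.finite(v)) {
      warning("non-finite cost; candidate rejected", call. = FALSE)
      return(Inf)
    }
    v
  }
  clamp <- function(x) pmin(ub, pmax(lb, x))

  with_seed(params$seed, {
    X <- matrix(stats::runif(N * dim, rep(lb, each = N), rep(ub, each = N)),
                N, dim)
    cost <- apply(X, 1, evaluate)
    best_i <- which.min(cost)
    x_best <- X[best_i, ]; c_best <- cost[best_i]
    history <- data.frame(iteration = 0L, best_cost = c_best,
                          mean_cost = mean(cost[is.finite(cost)]),
                          energy = NA_real_)
    for (t in seq_len(T_)) {
      e0 <- if (params$e0_mode == "resample") stats::runif(1, -1, 1) else params$e0_init
      E <- escape_energy(e0, t, T_)
      x_mean <- mean_position(X)
      for (i in seq_len(N)) {
        if (abs(E) >= 1) {
          x_new <- clamp(exploration_step(
            X[i, ], X[sample.int(N, 1L), ], x_best, x_mean, lb, ub))
          c_new <- evaluate(x_new)
          X[i, ] <- x_new; cost[i] <- c_new
        } else {
          r <- stats::runif(1)
          j <- 2 * (1 - stats::runif(1))
          if (r >= 0.5) {
            x_new <- clamp(if (abs(E) >= 0.5) {
              soft_besiege(X[i, ], x_best, E, j)
            } else {
              hard_besiege(X[i, ], x_best, E)
            })
            c_new <- evaluate(x_new)
            X[i, ] <- x_new; cost[i] <- c_new
          } else {
            # rapid dive: greedy acceptance of the better candidate
            y <- clamp(rapid_dive_step(x_best, x_mean, E, j))
            c_y <- evaluate(y)
            if (params$levy_dives) {
              z <- clamp(y + stats::runif(dim) * levy_step(dim))
              c_z <- evaluate(z)
              if (c_z < c_y) { y <- z; c_y <- c_z }
            }
            if (c_y < cost[i]) { X[i, ] <- y; cost[i] <- c_y }
          }
        }
        if (cost[i] < c_best) { c_best <- cost[i]; x_best <- X[i, ] }
      }
      history <- rbind(history, data.frame(
        iteration = t, best_cost = c_best,
        mean_cost = mean(cost[is.finite(cost)]), energy = E))
    }
    structure(list(best_position = x_best, best_cost = c_best,
                   history = history, n_evals = n_evals),
              class = "hho_result")
  })
}

#' Uniform random-search baseline
#'
#' Draws `n_evals` uniform points in the box and keeps the best; the
#' equal-budget control used to benchmark [hho_minimize()].
#'
#' @param cost_fn Cost function.
#' @param dim Dimension.
#' @param n_evals Evaluation budget.
#' @param lb,ub Bounds (scalars recycled).
#' @param seed RNG seed.
#' @return List with `best_position`, `best_cost`.
#' @export
random_search_minimize <- function(cost_fn, dim, n_evals, lb = 0, ub = 1,
                                   seed = NULL) {
  lb <- rep_len(lb, dim); ub <- rep_len(ub, dim)
  with_seed(seed, {
    best <- Inf; best_x <- NULL
    for (k in seq_len(n_evals)) {
      x <- stats::runif(dim, lb, ub)
      v <- cost_fn(x)
      if (is.finite(v) && v < best) { best <- v; best_x <- x }
    }
    list(best_position = best_x, best_cost = best)
  })
}

#' Write a convergence history to CSV
#'
#' @param result An [hho_minimize()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_convergence_history <- function(result, path) {
  utils::write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}
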