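# Bounded-box metaheuristic minimizers ----------------------------------
#
# Harmony search is the workhorse; real-coded GA and global-best PSO are
# provided as baselines with the comparison settings used throughout the
# package.  All three are seedable, respect box bounds for every evaluated
# candidate, and return monotone incumbent-best fitness traces.

#' Harmony search configuration
#'
#' @param hms Harmony memory size (>= 2; default 15).
#' @param hmcr Harmony memory consideration rate in \[0, 1\].  Default 0.8
#'   (the nested-design setting); 0.2 is the small-problem preset.
#' @param par Pitch adjustment rate in \[0, 1\] (default 0.2).
#' @param bw_frac Pitch bandwidth as a fraction of the box width per
#'   dimension (default 0.05).
#' @param max_iter Number of improvisations (default 2000).
#' @param seed RNG seed.
#' @return An `hs_config` list.
#' @export
hs_config <- function(hms = 15, hmcr = 0.8, par = 0.2, bw_frac = 0.05,
                      max_iter = 2000, seed = 1L) {
  stopifnot(hms >= 2, hmcr >= 0, hmcr <= 1, par >= 0, par <= 1,
            bw_frac >= 0, max_iter >= 1)
  structure(list(hms = as.integer(hms), hmcr = hmcr, par = par,
                 bw_frac = bw_frac, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "hs_config")
}

new_opt_result <- function(method, par, value, trace, evaluations, seed,
                           discarded = 0L) {
  structure(
    list(method = method, best_par = par, best_value = value,
         trace = trace, evaluations = evaluations, seed = seed,
         discarded = discarded),
    class = "opt_result"
  )
}

check_bounds <- function(lower, upper) {
  if (length(lower) != length(upper) || any(!is.finite(lower)) ||
      any(!is.finite(upper)) || any(lower >= upper)) {
    stop("`lower` and `upper` must be finite with lower < upper.",
         call. = FALSE)
  }
}

#' Minimize a function by harmony search
#'
#' Standard harmony search over a box: the harmony memory is initialized
#' with `hms` uniform random vectors (row 1 seeded by `incumbent` when
#' supplied); each iteration improvises one candidate -- per dimension,
#' with probability `hmcr` a value is drawn from the memory and then with
#' probability `par` pitch-adjusted by a uniform step of up to
#' `bw_frac * (upper - lower)`, otherwise the value is drawn uniformly
#' from the box.  The candidate replaces the worst memory row only on
#' strict improvement (ties keep the earlier row).  Candidates with a
#' non-finite objective are discarded (with a warning).
#'
#' @param objective Function of a numeric vector returning a scalar.
#' @param lower,upper Box bounds, one entry per dimension.
#' @param config An [hs_config()].
#' @param incumbent Optional start vector seeding memory row 1.
#' @return An `opt_result`: `best_par`, `best_value`, `trace` (incumbent
#'   best fitness per iteration, non-increasing), `evaluations`, `seed`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' r <- hs_minimize(sphere, rep(-5, 3), rep(5, 3),
#'                  hs_config(max_iter = 500, seed = 7))
#' r$best_value
#' @export
hs_minimize <- function(objective, lower, upper, config = hs_config(),
                        incumbent = NULL) {
  check_bounds(lower, upper)
  n <- length(lower)
  width <- upper - lower
  with_seed(config$seed, {
    HM <- matrix(stats::runif(config$hms * n), config$hms, n)
    HM <- sweep(sweep(HM, 2, width, "*"), 2, lower, "+")
    if (!is.null(incumbent)) {
      stopifnot(length(incumbent) == n)
      HM[1, ] <- pmin(pmax(incumbent, lower), upper)
    }
    fit <- apply(HM, 1, objective)
    discarded <- sum(!is.finite(fit))
    fit[!is.finite(fit)] <- Inf
    evals <- config$hms
    best_i <- which.min(fit)
    best <- HM[best_i, ]; best_f <- fit[best_i]
    trace <- numeric(config$max_iter)
    for (it in seq_len(config$max_iter)) {
      x <- numeric(n)
      for (j in seq_len(n)) {
        if (stats::runif(1) < config$hmcr) {
          xj <- HM[sample.int(config$hms, 1L), j]
          if (stats::runif(1) < config$par) {
            xj <- xj + (2 * stats::runif(1) - 1) * config$bw_frac * width[j]
            xj <- min(max(xj, lower[j]), upper[j])
          }
        } else {
          xj <- lower[j] + stats::runif(1) * width[j]
        }
        x[j] <- xj
      }
      f <- objective(x)
      evals <- evals + 1L
      if (!is.finite(f)) {
        discarded <- discarded + 1L
      } else {
        worst <- which.max(fit)
        if (f < fit[worst]) {
          HM[worst, ] <- x
          fit[worst] <- f
        }
        if (f < best_f) {
          best_f <- f
          best <- x
        }
      }
      trace[it] <- best_f
    }
    if (discarded > 0L) {
      warning(sprintf("harmony search: %d candidate(s) discarded (non-finite objective).",
                      discarded), call. = FALSE)
    }
    new_opt_result("harmony_search", best, best_f, trace, evals,
                   config$seed, discarded)
  })
}

#' Minimize a function by a real-coded genetic algorithm
#'
#' Tournament selection (size 2), arithmetic crossover, Gaussian mutation
#' (sd `mut_sd_frac` of the box width, clipped to bounds) and elitism of
#' one.  The default rates follow the package's comparison settings
#' (`mut_rate = 0.8`, `cross_rate = 0.2`); note conventional GA usage
#' often reverses the two, so both are exposed.
#'
#' @inheritParams hs_minimize
#' @param pop_size Population size (default 50).
#' @param mut_rate Per-gene mutation probability.
#' @param cross_rate Crossover probability per offspring.
#' @param mut_sd_frac Mutation step (fraction of box width).
#' @param max_iter Number of generations.
#' @param seed RNG seed.
#' @return An `opt_result` (trace = best fitness per generation).
#' @export
ga_minimize <- function(objective, lower, upper, pop_size = 50,
                        mut_rate = 0.8, cross_rate = 0.2,
                        mut_sd_frac = 0.1, max_iter = 200, seed = 1L) {
  check_bounds(lower, upper)
  n <- length(lower)
  width <- upper - lower
  with_seed(seed, {
    pop <- matrix(stats::runif(pop_size * n), pop_size, n)
    pop <- sweep(sweep(pop, 2, width, "*"), 2, lower, "+")
    fit <- apply(pop, 1, objective)
    discarded <- sum(!is.finite(fit))
    fit[!is.finite(fit)] <- Inf
    evals <- pop_size
    trace <- numeric(max_iter)
    for (gen in seq_len(max_iter)) {
      elite_i <- which.min(fit)
      newpop <- matrix(NA_real_, pop_size, n)
      newpop[1, ] <- pop[elite_i, ]
      for (k in 2:pop_size) {
        i1 <- sample.int(pop_size, 2); i2 <- sample.int(pop_size, 2)
        p1 <- pop[i1[which.min(fit[i1])], ]
        p2 <- pop[i2[which.min(fit[i2])], ]
        child <- if (stats::runif(1) < cross_rate) {
          a <- stats::runif(1)
          a * p1 + (1 - a) * p2
        } else p1
        mut <- stats::runif(n) < mut_rate
        if (any(mut)) {
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0, mut_sd_frac * width[mut])
        }
        newpop[k, ] <- pmin(pmax(child, lower), upper)
      }
      pop <- newpop
      fit <- apply(pop, 1, objective)
      discarded <- discarded + sum(!is.finite(fit))
      fit[!is.finite(fit)] <- Inf
      evals <- evals + pop_size
      trace[gen] <- min(fit)
    }
    trace <- cummin(trace)
    best_i <- which.min(fit)
    if (discarded > 0L) {
      warning(sprintf("GA: %d candidate(s) discarded (non-finite objective).",
                      discarded), call. = FALSE)
    }
    new_opt_result("genetic_algorithm", pop[best_i, ], min(trace), trace,
                   evals, as.integer(seed), discarded)
  })
}

#' Minimize a function by global-best particle swarm optimization
#'
#' Velocity update `v <- weight * v + c1 r1 (pbest - x) + c2 r2 (gbest -
#' x)` with velocities clamped to half the box width per dimension and
#' positions clipped to the bounds.  Defaults follow the package's
#' comparison settings (`weight = 1`, `c1 = c2 = 1`).
#'
#' @inheritParams hs_minimize
#' @param swarm_size Number of particles (default 50).
#' @param weight Inertia weight.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param max_iter Number of iterations.
#' @param seed RNG seed.
#' @return An `opt_result` (trace = global-best fitness per iteration).
#' @export
pso_minimize <- function(objective, lower, upper, swarm_size = 50,
                         weight = 1, c1 = 1, c2 = 1, max_iter = 200,
                         seed = 1L) {
  check_bounds(lower, upper)
  n <- length(lower)
  width <- upper - lower
  vmax <- 0.5 * width
  with_seed(seed, {
    X <- matrix(stats::runif(swarm_size * n), swarm_size, n)
    X <- sweep(sweep(X, 2, width, "*"), 2, lower, "+")
    V <- matrix(stats::runif(swarm_size * n, -1, 1), swarm_size, n)
    V <- sweep(V, 2, vmax, "*")
    fit <- apply(X, 1, objective)
    discarded <- sum(!is.finite(fit))
    fit[!is.finite(fit)] <- Inf
    evals <- swarm_size
    P <- X; pfit <- fit
    g_i <- which.min(pfit)
    gbest <- P[g_i, ]; gfit <- pfit[g_i]
    trace <- numeric(max_iter)
    for (it in seq_len(max_iter)) {
      r1 <- matrix(stats::runif(swarm_size * n), swarm_size, n)
      r2 <- matrix(stats::runif(swarm_size * n), swarm_size, n)
      V <- weight * V + c1 * r1 * (P - X) +
        c2 * r2 * (matrix(gbest, swarm_size, n, byrow = TRUE) - X)
      V <- pmin(pmax(V, matrix(-vmax, swarm_size, n, byrow = TRUE)),
                matrix(vmax, swarm_size, n, byrow = TRUE))
      X <- X + V
      X <- pmin(pmax(X, matrix(lower, swarm_size, n, byrow = TRUE)),
                matrix(upper, swarm_size, n, byrow = TRUE))
      fit <- apply(X, 1, objective)
      discarded <- discarded + sum(!is.finite(fit))
      fit[!is.finite(fit)] <- Inf
      evals <- evals + swarm_size
      improved <- fit < pfit
      P[improved, ] <- X[improved, ]
      pfit[improved] <- fit[improved]
      if (min(pfit) < gfit) {
        g_i <- which.min(pfit)
        gbest <- P[g_i, ]; gfit <- pfit[g_i]
      }
      trace[it] <- gfit
    }
    if (discarded > 0L) {
      warning(sprintf("PSO: %d candidate(s) discarded (non-finite objective).",
                      discarded), call. = FALSE)
    }
    new_opt_result("particle_swarm", gbest, gfit, trace, evals,
                   as.integer(seed), discarded)
  })
}

#' @export
print.opt_result <- function(x, ...) {
  cat("<opt_result>", x$method, ": best fitness",
      format(x$best_value, digits = 6), "after", x$evaluations,
      "evaluations\n")
  invisible(x)
}

#' Fitness trace of an optimizer run
#'
#' @param x An `opt_result`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `best_fitness`.
#' @export
tidy.opt_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$trace), best_fitness = x$trace)
}

#' @export
glance.opt_result <- function(x, ...) {
  tibble::tibble(method = x$method, best_fitness = x$best_value,
                 evaluations = x$evaluations, seed = x$seed,
                 discarded = x$discarded)
}

#' Write an optimizer fitness trace as CSV
#'
#' @inheritParams tidy.opt_result
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  utils::write.csv(as.data.frame(tidy.opt_result(x)), path,
                   row.names = FALSE)
  invisible(path)
}
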