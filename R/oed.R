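# Two-stage nested optimal experimental design --------------------------
#
# The outer loop searches the induction level u (uM) by harmony search,
# scoring each candidate with the modified E-optimality criterion of the
# Fisher matrix evaluated at the inner loop's parameter estimate; the
# inner loop fits the free kinetic parameters to synthetic measurements
# generated under that u (weighted least squares, again by harmony
# search).  Measurements for a candidate u are regenerated from a seed
# derived deterministically from (master seed, u), so the outer objective
# is a deterministic function of u and memory comparisons are not
# noise-dominated.

#' Design space for input-level selection
#'
#' @param input_kind Waveform applied during the designed experiment
#'   (default `"step"`; the outer loop optimizes its magnitude).
#' @param u_lb,u_ub Feasible induction-level interval in uM (default
#'   \[1, 30\]).
#' @param t_f Experiment duration in minutes (default 3000).
#' @param n_m Number of measured time points per candidate experiment
#'   (default 50).
#' @param n_m_grid Candidate sample sizes for [select_sample_size()]
#'   (default 10 to 100 in steps of 10).
#' @param lambda Measurement-cost penalty coefficient (default 0.8).
#' @return A `design_space` list.
#' @export
design_space <- function(input_kind = "step", u_lb = 1, u_ub = 30,
                         t_f = 3000, n_m = 50,
                         n_m_grid = seq(10, 100, by = 10), lambda = 0.8) {
  stopifnot(u_lb <= u_ub, u_lb >= 0, t_f > 0, n_m >= 2)
  structure(list(input_kind = input_kind, u_lb = u_lb, u_ub = u_ub,
                 t_f = t_f, n_m = n_m, n_m_grid = n_m_grid,
                 lambda = lambda),
            class = "design_space")
}

#' Default search box for kinetic parameters
#'
#' A generous multiplicative box around the reference value per parameter
#' (default one fifth to five times), intersected with the phosphotransfer
#' range \[1, 50\] for `k1..k4` of the buffered circuit.  The box plays
#' the role of the biological prior that bounds any realistic rate; a
#' tighter box speeds refinement, a wider one weakens it.
#'
#' @param model A [circuit_model()].
#' @param free Parameter names to bound.
#' @param span Multiplicative factors `c(lower, upper)` applied to the
#'   reference values.
#' @return List with named vectors `lower` and `upper`.
#' @export
default_param_bounds <- function(model, free = model$param_names,
                                 span = c(0.2, 5)) {
  p <- model$params[free]
  lower <- p * span[1]
  upper <- p * span[2]
  if (model$name == "buffered") {
    hard <- intersect(free, c("k1", "k2", "k3", "k4"))
    lower[hard] <- pmax(lower[hard], 1)
    upper[hard] <- pmin(upper[hard], 50)
  }
  list(lower = lower, upper = upper)
}

# Weighted residual sum between a measurement set and the model response
# at candidate parameters; +Inf sentinel on simulation failure.  Noiseless
# points (std 0) get unit weight.
measurement_objective <- function(model, input, measurements, free,
                                  rtol = 1e-6, atol = 1e-8) {
  times <- measurements$time
  grid <- sort(unique(c(0, times)))
  idx <- match(times, grid)
  sig <- ifelse(measurements$std > 0, measurements$std, 1)
  y <- measurements$value
  p_full <- model$params
  obs <- model$state_names[model$observable]
  function(theta) {
    p_full[free] <- theta
    out <- tryCatch({
      tr <- simulate_trajectory(model, input, grid, params = p_full,
                                rtol = rtol, atol = atol)
      wrsse(y, tr[[obs]][idx], sig)
    }, error = function(e) Inf)
    out
  }
}

#' Inner-loop parameter estimation by harmony search
#'
#' Minimizes the weighted residual sum of squares between a measurement
#' set and the simulated GFP response over a box of free kinetic
#' parameters.
#'
#' @param model A [circuit_model()] (its `params` supply the fixed
#'   values of parameters not in `free`).
#' @param input The [input_signal][make_input] the measurements were
#'   collected under.
#' @param measurements A `measurement_set` (see
#'   [generate_measurements()]).
#' @param free Names of the parameters to estimate.
#' @param bounds List with `lower`/`upper` named vectors; default
#'   [default_param_bounds()].
#' @param config An [hs_config()] for the search.
#' @param incumbent Optional start vector seeding the harmony memory.
#' @param rtol,atol Solver tolerances used inside the objective.
#' @return List with `par` (named estimate), `wrsse` (best fitness),
#'   `opt` (the full `opt_result`) and `trace`.
#' @examples
#' mod <- circuit_model("unbuffered")
#' u <- make_input("step", 20)
#' m <- generate_measurements(mod, u, n_m = 15, t_f = 600, seed = 2)
#' fit <- inner_estimate(mod, u, m, free = c("k_on", "k_off"),
#'                       config = hs_config(max_iter = 50, seed = 3))
#' fit$par
#' @export
inner_estimate <- function(model, input, measurements,
                           free = model$param_names,
                           bounds = default_param_bounds(model, free),
                           config = hs_config(), incumbent = NULL,
                           rtol = 1e-6, atol = 1e-8) {
  obj <- measurement_objective(model, input, measurements, free,
                               rtol, atol)
  res <- hs_minimize(obj, bounds$lower[free], bounds$upper[free],
                     config = config, incumbent = incumbent)
  par <- stats::setNames(res$best_par, free)
  list(par = par, wrsse = res$best_value, opt = res, trace = res$trace)
}

#' Two-stage nested input-level design (outer loop)
#'
#' Selects the induction level \eqn{u^*} within the feasible interval by
#' harmony search.  Every candidate u is scored by: (1) generating
#' synthetic measurements under u with a seed derived from
#' `(seed, round(u, 2))`; (2) estimating the free parameters by
#' [inner_estimate()], with the current incumbent estimate seeding the
#' memory; (3) computing the Fisher matrix of the design at the estimate
#' and returning its modified-E criterion (optionally plus the fit
#' wRSSE when `combine = TRUE`).  The incumbent pair (u*, p*) is updated
#' only on strict criterion improvement.
#'
#' @param model A [circuit_model()]; its `params` act as the data
#'   generating truth for the synthetic measurements.
#' @param design A [design_space()].
#' @param free Parameters to estimate (default: all).
#' @param bounds Parameter search box (default [default_param_bounds()]).
#' @param outer_config,inner_config [hs_config()]s for the two loops (the
#'   inner seed is re-derived per candidate u).
#' @param noise A [noise_model()].
#' @param seed Master seed; fixes the whole nested run.
#' @param combine Add the inner wRSSE to the outer criterion?
#' @param sens_rtol,sens_atol Tolerances for the sensitivity integration
#'   behind the Fisher matrix.
#' @return An `oed_result`: `u_star`, `p_star`, `criterion_star`,
#'   `outer` (`opt_result` over u), `evaluations` (tibble of every
#'   distinct candidate u with its criterion and wRSSE), `fim_at_optimum`,
#'   `design`, `seed`.
#' @export
outer_design <- function(model, design = design_space(),
                         free = model$param_names,
                         bounds = default_param_bounds(model, free),
                         outer_config = hs_config(hmcr = 0.8, max_iter = 30),
                         inner_config = hs_config(hmcr = 0.8,
                                                  max_iter = 300),
                         noise = noise_model(), seed = 1L,
                         combine = FALSE,
                         sens_rtol = 1e-6, sens_atol = 1e-8) {
  true_params <- model$params
  cache <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  state$p_star <- NULL
  state$c_star <- Inf
  state$rows <- list()

  eval_candidate <- function(u) {
    u <- round(u, 2)
    key <- sprintf("%.2f", u)
    if (!is.null(cache[[key]])) return(cache[[key]]$criterion)
    res <- score_input_level(model, u, design, free, bounds,
                             inner_config, noise, seed,
                             incumbent = state$p_star,
                             combine = combine,
                             sens_rtol = sens_rtol, sens_atol = sens_atol)
    cache[[key]] <- res
    state$rows[[key]] <- tibble::tibble(
      u = u, criterion = res$criterion, modE = res$modE,
      wrsse = res$wrsse
    )
    if (res$criterion < state$c_star) {
      state$c_star <- res$criterion
      state$p_star <- res$par
    }
    res$criterion
  }

  if (design$u_lb == design$u_ub) {
    # degenerate design space: a single candidate level
    crit <- eval_candidate(design$u_lb)
    outer <- new_opt_result("harmony_search", design$u_lb, crit, crit,
                            1L, as.integer(outer_config$seed))
  } else {
    outer <- hs_minimize(eval_candidate, design$u_lb, design$u_ub,
                         config = outer_config)
  }
  u_star <- round(outer$best_par, 2)
  best <- cache[[sprintf("%.2f", u_star)]]
  evals <- dplyr::arrange(dplyr::bind_rows(state$rows), .data$u)
  structure(
    list(u_star = u_star, p_star = best$par,
         criterion_star = best$criterion,
         outer = outer, evaluations = evals,
         fim_at_optimum = best$fim, inner_trace = best$trace,
         free = free, design = design, seed = as.integer(seed),
         model_name = model$name, true_params = true_params),
    class = "oed_result"
  )
}

# Score one candidate input level: synthetic data, inner fit, FIM.
score_input_level <- function(model, u, design, free, bounds,
                              inner_config, noise, seed, incumbent = NULL,
                              combine = FALSE,
                              sens_rtol = 1e-6, sens_atol = 1e-8) {
  seed_u <- derive_seed(seed, u)
  input <- make_input(design$input_kind, magnitude = u)
  meas <- tryCatch(
    generate_measurements(model, input, n_m = design$n_m,
                          t_f = design$t_f, noise = noise, seed = seed_u),
    error = function(e) NULL
  )
  if (is.null(meas)) {
    return(list(criterion = Inf, modE = Inf, wrsse = Inf, par = incumbent,
                fim = NULL, trace = numeric(0)))
  }
  cfg <- inner_config
  cfg$seed <- derive_seed(seed_u, 1)
  fit <- inner_estimate(model, input, meas, free = free, bounds = bounds,
                        config = cfg, incumbent = incumbent)
  fim <- tryCatch({
    p_fit <- model$params
    p_fit[free] <- fit$par
    S <- forward_sensitivities(model, input, meas$time, params = p_fit,
                               free = free, rtol = sens_rtol,
                               atol = sens_atol)
    sig <- ifelse(meas$std > 0, meas$std, 1)
    fisher_information(S, sig)
  }, error = function(e) NULL)
  modE <- if (is.null(fim)) Inf else fim$criteria[["modE"]]
  crit <- if (combine) modE + fit$wrsse else modE
  list(criterion = crit, modE = modE, wrsse = fit$wrsse, par = fit$par,
       fim = fim, trace = fit$trace)
}

#' Exhaustive input-level screening
#'
#' Brute-force counterpart of [outer_design()]: scores every u in
#' `u_grid` with the same per-u measurement seeds and inner estimation,
#' and returns the grid minimizer.  Useful as a reference for the harmony
#' search outer loop on small problems.
#'
#' @inheritParams outer_design
#' @param u_grid Candidate induction levels (uM).
#' @return List with `u_star`, `p_star`, and `evaluations` (tibble).
#' @export
screen_input_levels <- function(model, u_grid, design = design_space(),
                                free = model$param_names,
                                bounds = default_param_bounds(model, free),
                                inner_config = hs_config(hmcr = 0.8,
                                                         max_iter = 300),
                                noise = noise_model(), seed = 1L,
                                combine = FALSE,
                                sens_rtol = 1e-6, sens_atol = 1e-8) {
  rows <- list()
  best <- list(criterion = Inf, par = NULL, u = NA_real_)
  for (u in round(u_grid, 2)) {
    res <- score_input_level(model, u, design, free, bounds, inner_config,
                             noise, seed, incumbent = NULL,
                             combine = combine, sens_rtol = sens_rtol,
                             sens_atol = sens_atol)
    rows[[sprintf("%.2f", u)]] <- tibble::tibble(
      u = u, criterion = res$criterion, modE = res$modE, wrsse = res$wrsse
    )
    if (res$criterion < best$criterion) {
      best <- list(criterion = res$criterion, par = res$par, u = u)
    }
  }
  list(u_star = best$u, p_star = best$par,
       criterion_star = best$criterion,
       evaluations = dplyr::bind_rows(rows))
}

#' Sample-size selection by the accuracy-vs-cost objective
#'
#' For every candidate sample size in `n_m_grid`: measurements are taken
#' at evenly spaced times over `[0, t_f]`, the free parameters are
#' re-fit (harmony memory seeded with `p_init`), and the cost
#' \eqn{J(n_m)} of [sample_size_cost()] is evaluated.  The minimizing
#' sample size (first index on ties) and the full cost curve are
#' returned.
#'
#' @inheritParams outer_design
#' @param input The [input_signal][make_input] for the experiment.
#' @param n_m_grid Candidate numbers of time points (each > number of
#'   free parameters).
#' @param lambda Penalty coefficient (default from `design`).
#' @param p_init Start vector for the re-fits (defaults to the model's
#'   parameters).
#' @param weighted Use sigma-weighted residuals in the accuracy term?
#' @return A `sample_size_result`: `n_m_star`, `cost_curve` tibble
#'   (`n_m`, `J`, `accuracy`, `penalty`), `fits` (list of estimates),
#'   `lambda`, `seed`.
#' @export
select_sample_size <- function(model, input, design = design_space(),
                               n_m_grid = design$n_m_grid,
                               lambda = design$lambda,
                               free = model$param_names,
                               bounds = default_param_bounds(model, free),
                               inner_config = hs_config(hmcr = 0.8,
                                                        max_iter = 300),
                               noise = noise_model(), seed = 1L,
                               p_init = model$params[free],
                               weighted = FALSE) {
  n_p <- length(free)
  if (any(n_m_grid <= n_p)) {
    stop("Every candidate sample size must exceed the number of free ",
         "parameters (", n_p, ").", call. = FALSE)
  }
  obs <- model$state_names[model$observable]
  rows <- list()
  fits <- list()
  for (n_m in n_m_grid) {
    seed_n <- derive_seed(seed, n_m)
    meas <- generate_measurements(model, input, n_m = n_m,
                                  t_f = design$t_f, noise = noise,
                                  seed = seed_n)
    cfg <- inner_config
    cfg$seed <- derive_seed(seed_n, 1)
    fit <- inner_estimate(model, input, meas, free = free,
                          bounds = bounds, config = cfg,
                          incumbent = as.numeric(p_init))
    p_fit <- model$params
    p_fit[free] <- fit$par
    grid <- sort(unique(c(0, meas$time)))
    tr <- simulate_trajectory(model, input, grid, params = p_fit,
                              rtol = 1e-6, atol = 1e-8)
    residuals <- meas$value - tr[[obs]][match(meas$time, tr$time)]
    sig <- ifelse(meas$std > 0, meas$std, 1)
    cost <- sample_size_cost(residuals, n_m, n_p, lambda, sigma = sig,
                             weighted = weighted)
    rows[[as.character(n_m)]] <- tibble::tibble(
      n_m = n_m, J = cost$J, accuracy = cost$accuracy,
      penalty = cost$penalty
    )
    fits[[as.character(n_m)]] <- fit$par
  }
  curve <- dplyr::bind_rows(rows)
  n_m_star <- curve$n_m[which.min(curve$J)]
  structure(
    list(n_m_star = n_m_star, cost_curve = curve, fits = fits,
         lambda = lambda, seed = as.integer(seed), free = free),
    class = "sample_size_result"
  )
}

#' Steady-state input-output screening
#'
#' Simulates the circuit to steady state under constant DOX levels and
#' tabulates the steady GFP output and the output-input gain.  The gain
#' declines once the Hill activation saturates, which is what makes an
#' intermediate induction level informative.
#'
#' @param model A [circuit_model()].
#' @param dox_levels Positive DOX concentrations (uM).
#' @param t_f Horizon used to reach steady state (default 3000 min).
#' @param steady_tol Relative derivative threshold flagging non-steady
#'   trajectories.
#' @return Tibble of class `dose_response` with columns `dox`,
#'   `steady_gfp`, `gain` and `steady` (logical flag).
#' @examples
#' dose_response(circuit_model("unbuffered"), c(0.1, 1, 10))
#' @export
dose_response <- function(model, dox_levels, t_f = 3000,
                          steady_tol = 1e-6) {
  if (any(dox_levels <= 0)) {
    stop("`dox_levels` must be positive (the gain is undefined at 0; ",
         "the zero-input baseline is k_sgfp / delta_G).", call. = FALSE)
  }
  obs <- model$state_names[model$observable]
  rows <- lapply(dox_levels, function(d) {
    tr <- simulate_trajectory(model, make_input("constant", d),
                              c(0, t_f / 2, t_f))
    g <- tr[[obs]][3]
    rate <- abs(circuit_rhs_fn(model)(
      unlist(tr[3, model$state_names]), t_f, model$params,
      model$constants, d, model$load_factor
    )[model$observable])
    tibble::tibble(dox = d, steady_gfp = g, gain = g / d,
                   steady = rate <= steady_tol * max(abs(g), 1))
  })
  out <- dplyr::bind_rows(rows)
  if (any(!out$steady)) {
    warning("Some trajectories had not reached steady state by t_f; ",
            "see the `steady` column.", call. = FALSE)
  }
  structure(out, class = c("dose_response", class(out)))
}

#' Compare harmony search with GA and PSO on the inner fit
#'
#' Runs the three optimizers on the same weighted least-squares parameter
#' estimation problem with a shared evaluation budget.
#'
#' @inheritParams inner_estimate
#' @param max_iter Harmony-search improvisations; GA/PSO generations are
#'   scaled down to match the evaluation budget.
#' @param seed Shared seed.
#' @return List with `summary` (tibble: method, best fitness,
#'   evaluations) and `runs` (named list of `opt_result`s).
#' @export
benchmark_optimizers <- function(model, input, measurements,
                                 free = model$param_names,
                                 bounds = default_param_bounds(model, free),
                                 max_iter = 600, seed = 1L) {
  obj <- measurement_objective(model, input, measurements, free)
  lo <- bounds$lower[free]; up <- bounds$upper[free]
  pop <- 50L
  gens <- max(2L, ceiling(max_iter / pop))
  runs <- list(
    harmony_search = hs_minimize(obj, lo, up,
                                 hs_config(max_iter = max_iter,
                                           seed = seed)),
    genetic_algorithm = ga_minimize(obj, lo, up, pop_size = pop,
                                    max_iter = gens, seed = seed),
    particle_swarm = pso_minimize(obj, lo, up, swarm_size = pop,
                                  max_iter = gens, seed = seed)
  )
  summary <- dplyr::bind_rows(lapply(runs, glance.opt_result))
  list(summary = summary, runs = runs)
}

# S3 methods -------------------------------------------------------------

#' @export
print.oed_result <- function(x, ...) {
  cat("<oed_result>", x$model_name, "circuit: u* =", x$u_star,
      "uM; criterion =", format(x$criterion_star, digits = 5), "\n")
  invisible(x)
}

#' Candidate-level view of a nested design run
#'
#' @param x An `oed_result`.
#' @param ... Unused.
#' @return Tibble of all evaluated input levels with their criterion,
#'   modified-E value and inner-fit wRSSE.
#' @export
tidy.oed_result <- function(x, ...) {
  x$evaluations
}

#' @export
glance.oed_result <- function(x, ...) {
  tibble::tibble(
    u_star = x$u_star, criterion = x$criterion_star,
    n_candidates = nrow(x$evaluations), seed = x$seed,
    model = x$model_name
  )
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat("<sample_size_result> n_m* =", x$n_m_star, "(lambda =", x$lambda,
      ")\n")
  invisible(x)
}

#' @export
tidy.sample_size_result <- function(x, ...) {
  x$cost_curve
}

#' @export
glance.sample_size_result <- function(x, ...) {
  tibble::tibble(n_m_star = x$n_m_star, lambda = x$lambda,
                 J_min = min(x$cost_curve$J), seed = x$seed)
}
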