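test_that("a perfect start leaves the inner estimate at the truth", {
  m <- unbuf()
  free <- c("k_on", "k_off")
  meas <- generate_measurements(m, step20(), n_m = 10, t_f = 600,
                                noise = noiseless(), seed = 1)
  fit <- inner_estimate(m, step20(), meas, free = free,
                        config = hs_config(max_iter = 30, seed = 2),
                        incumbent = as.numeric(m$params[free]))
  expect_lt(fit$wrsse, 1e-10)
  expect_equal(as.numeric(fit$par), as.numeric(m$params[free]),
               tolerance = 1e-10)
})

test_that("simulation failures inside the objective become +Inf sentinels", {
  m <- unbuf()
  meas <- generate_measurements(m, step20(), n_m = 8, t_f = 300, seed = 1)
  obj <- circuitOED:::measurement_objective(m, step20(), meas,
                                            free = "k_on")
  expect_equal(obj(-5), Inf)  # negative rate is rejected by validation
  expect_true(is.finite(obj(0.2)))
})

test_that("a collapsed design space returns its single candidate", {
  m <- unbuf()
  des <- design_space(u_lb = 12, u_ub = 12, t_f = 400, n_m = 12)
  oed <- outer_design(m, des, free = c("k_on", "k_off"),
                      inner_config = hs_config(max_iter = 40, seed = 1),
                      seed = 5)
  expect_equal(oed$u_star, 12)
  expect_equal(nrow(oed$evaluations), 1)
  # the returned p_star is exactly the inner estimate for that u
  scr <- screen_input_levels(m, 12, design = des,
                             free = c("k_on", "k_off"),
                             inner_config = hs_config(max_iter = 40,
                                                      seed = 1),
                             seed = 5)
  expect_equal(oed$p_star, scr$p_star)
  expect_equal(oed$criterion_star, scr$criterion_star)
})

test_that("nested design runs are deterministic in the master seed", {
  m <- unbuf()
  des <- design_space(u_lb = 5, u_ub = 25, t_f = 400, n_m = 12)
  run <- function() {
    outer_design(m, des, free = c("k_on", "k_off"),
                 outer_config = hs_config(max_iter = 4, seed = 11),
                 inner_config = hs_config(max_iter = 25, seed = 1),
                 seed = 11)
  }
  a <- run(); b <- run()
  expect_identical(a$u_star, b$u_star)
  expect_identical(a$p_star, b$p_star)
  expect_identical(a$outer$trace, b$outer$trace)
  expect_identical(a$evaluations, b$evaluations)
  # outer incumbent trace is monotone
  expect_true(all(diff(a$outer$trace) <= 0))
})

test_that("noiseless data with the true parameters reduce the cost to its penalty", {
  m <- unbuf()
  free <- c("k_on", "k_off")
  des <- design_space(t_f = 600)
  grid <- seq(10, 60, by = 10)
  ss <- select_sample_size(m, step20(), design = des, n_m_grid = grid,
                           lambda = 0.8, free = free,
                           inner_config = hs_config(max_iter = 20),
                           noise = noiseless(), seed = 3)
  expect_equal(ss$cost_curve$J, 0.8 * (grid - 2) / grid,
               tolerance = 1e-8)
  expect_true(all(diff(ss$cost_curve$J) > 0))
  expect_equal(ss$n_m_star, 10)
})

test_that("with no penalty the residual term drives sample-size selection", {
  m <- unbuf()
  grid <- c(10, 20)
  ss <- select_sample_size(m, step20(), design = design_space(t_f = 600),
                           n_m_grid = grid, lambda = 0,
                           free = c("k_on", "k_off"),
                           inner_config = hs_config(max_iter = 20),
                           noise = noiseless(), seed = 3)
  expect_equal(ss$cost_curve$J, ss$cost_curve$accuracy)
  expect_equal(ss$cost_curve$penalty * 0, c(0, 0))
})

test_that("sample sizes not exceeding the parameter count are rejected", {
  m <- unbuf()
  expect_error(
    select_sample_size(m, step20(), n_m_grid = c(5, 9),
                       free = m$param_names),
    "must exceed"
  )
})

test_that("the selection sweep equals an independent re-run of its loop", {
  m <- unbuf()
  free <- c("k_on", "k_off")
  des <- design_space(t_f = 600)
  grid <- c(10, 20, 30)
  icfg <- hs_config(max_iter = 15)
  ss <- select_sample_size(m, step20(), design = des, n_m_grid = grid,
                           lambda = 0.8, free = free,
                           inner_config = icfg, seed = 13)
  # independent re-implementation of the sweep
  J_oracle <- vapply(grid, function(n_m) {
    seed_n <- circuitOED:::derive_seed(13, n_m)
    meas <- generate_measurements(m, step20(), n_m = n_m, t_f = des$t_f,
                                  seed = seed_n)
    cfg <- icfg; cfg$seed <- circuitOED:::derive_seed(seed_n, 1)
    fit <- inner_estimate(m, step20(), meas, free = free, config = cfg,
                          incumbent = as.numeric(m$params[free]))
    p <- m$params; p[free] <- fit$par
    tr <- simulate_trajectory(m, step20(),
                              sort(unique(c(0, meas$time))), params = p,
                              rtol = 1e-6, atol = 1e-8)
    r <- meas$value - tr$G[match(meas$time, tr$time)]
    sum(r^2) + 0.8 * (n_m - 2) / n_m
  }, numeric(1))
  expect_equal(ss$cost_curve$J, J_oracle, tolerance = 1e-10)
  expect_equal(ss$n_m_star, grid[which.min(J_oracle)])
})

test_that("steady GFP rises with DOX while the gain eventually falls", {
  m <- unbuf()
  levels <- 10^seq(-3, 2, length.out = 10)
  dr <- dose_response(m, levels)
  expect_true(all(diff(dr$steady_gfp) >= -1e-8))
  expect_true(all(dr$steady))
  # zero-input limit: basal production over degradation
  expect_equal(dr$steady_gfp[1],
               m$params[["k_sgfp"]] / m$params[["delta_G"]],
               tolerance = 1e-3)
  # once the response saturates the output-input ratio declines strictly
  sat <- which(dr$steady_gfp > 0.9 * max(dr$steady_gfp))
  expect_true(all(diff(dr$gain[sat]) < 0))
  expect_error(dose_response(m, c(0, 1)), "positive")
})

test_that("optimizer benchmark runs all three methods on one fit", {
  m <- unbuf()
  meas <- generate_measurements(m, step20(), n_m = 8, t_f = 400, seed = 2)
  b <- benchmark_optimizers(m, step20(), meas, free = "k_on",
                            max_iter = 60, seed = 3)
  expect_setequal(b$summary$method,
                  c("harmony_search", "genetic_algorithm",
                    "particle_swarm"))
  expect_true(all(is.finite(b$summary$best_fitness)))
  for (r in b$runs) expect_true(all(diff(r$trace) <= 0))
})
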