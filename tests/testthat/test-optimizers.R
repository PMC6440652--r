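sphere <- function(x) sum(x^2)

test_that("a constant objective returns the constant within bounds", {
  for (run in list(
    hs_minimize(function(x) 3.5, -1, 1, hs_config(max_iter = 50, seed = 1)),
    ga_minimize(function(x) 3.5, -1, 1, max_iter = 5, seed = 1),
    pso_minimize(function(x) 3.5, -1, 1, max_iter = 5, seed = 1)
  )) {
    expect_equal(run$best_value, 3.5)
    expect_true(all(run$best_par >= -1 & run$best_par <= 1))
  }
})

test_that("identical seeds give bit-identical traces", {
  cfg <- hs_config(max_iter = 300, seed = 99)
  a <- hs_minimize(sphere, rep(-5, 3), rep(5, 3), cfg)
  b <- hs_minimize(sphere, rep(-5, 3), rep(5, 3), cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_par, b$best_par)
  g1 <- ga_minimize(sphere, rep(-5, 3), rep(5, 3), max_iter = 20, seed = 7)
  g2 <- ga_minimize(sphere, rep(-5, 3), rep(5, 3), max_iter = 20, seed = 7)
  expect_identical(g1$trace, g2$trace)
  p1 <- pso_minimize(sphere, rep(-5, 3), rep(5, 3), max_iter = 20, seed = 7)
  p2 <- pso_minimize(sphere, rep(-5, 3), rep(5, 3), max_iter = 20, seed = 7)
  expect_identical(p1$trace, p2$trace)
})

test_that("every evaluated candidate respects the box", {
  seen <- list()
  watched <- function(x) {
    seen[[length(seen) + 1L]] <<- x
    sphere(x)
  }
  hs_minimize(watched, c(-1, 0), c(1, 2),
              hs_config(max_iter = 200, seed = 3))
  M <- do.call(rbind, seen)
  expect_true(all(M[, 1] >= -1 & M[, 1] <= 1))
  expect_true(all(M[, 2] >= 0 & M[, 2] <= 2))
})

test_that("incumbent traces are monotone non-increasing", {
  h <- hs_minimize(sphere, rep(-5, 3), rep(5, 3),
                   hs_config(max_iter = 500, seed = 5))
  g <- ga_minimize(sphere, rep(-5, 3), rep(5, 3), max_iter = 40, seed = 5)
  p <- pso_minimize(sphere, rep(-5, 3), rep(5, 3), max_iter = 40, seed = 5)
  for (r in list(h, g, p)) expect_true(all(diff(r$trace) <= 0))
})

test_that("harmony search solves the sphere to high precision", {
  r <- hs_minimize(sphere, rep(-5, 3), rep(5, 3),
                   hs_config(max_iter = 2000, seed = 17))
  expect_lt(r$best_value, 1e-2)
  # repeated seeds agree on the property, not just one lucky draw
  for (s in c(18, 19)) {
    expect_lt(hs_minimize(sphere, rep(-5, 3), rep(5, 3),
                          hs_config(max_iter = 2000,
                                    seed = s))$best_value, 1e-2)
  }
})

test_that("GA and PSO solve the sphere at their benchmark settings", {
  expect_lt(ga_minimize(sphere, rep(-5, 3), rep(5, 3), max_iter = 40,
                        seed = 21)$best_value, 1e-1)
  expect_lt(pso_minimize(sphere, rep(-5, 3), rep(5, 3), max_iter = 40,
                         seed = 21)$best_value, 1e-1)
})

test_that("harmony search restricted to a grid finds the enumerated optimum", {
  grid <- seq(-5, 5, length.out = 101)
  f <- function(x) (x - 1.7)^2 + 0.3 * sin(5 * x)
  snapped <- function(x) f(grid[which.min(abs(grid - x))])
  oracle <- min(vapply(grid, f, numeric(1)))
  r <- hs_minimize(function(x) snapped(x), -5, 5,
                   hs_config(max_iter = 2000, seed = 23))
  expect_equal(r$best_value, oracle)
})

test_that("an incumbent seeds the harmony memory", {
  r <- hs_minimize(sphere, rep(-5, 3), rep(5, 3),
                   hs_config(max_iter = 1, seed = 2),
                   incumbent = c(0, 0, 0))
  expect_equal(r$best_value, 0)
})

test_that("non-finite candidates are discarded with a warning", {
  bad <- function(x) if (x[1] > 0) Inf else sphere(x)
  expect_warning(
    r <- hs_minimize(bad, -1, 1, hs_config(max_iter = 100, seed = 4)),
    "discarded"
  )
  expect_true(is.finite(r$best_value))
  expect_true(r$best_par <= 0)
})

test_that("config invariants are enforced", {
  expect_error(hs_config(hms = 1), "hms")
  expect_error(hs_config(hmcr = 1.2), "hmcr")
  expect_error(hs_minimize(sphere, c(0, 0), c(1, -1)), "lower < upper")
})

test_that("tidy and glance expose the trace and summary", {
  r <- hs_minimize(sphere, -1, 1, hs_config(max_iter = 25, seed = 1))
  td <- tidy(r)
  expect_equal(nrow(td), 25)
  expect_named(td, c("iteration", "best_fitness"))
  gl <- glance(r)
  expect_equal(gl$method, "harmony_search")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(r, path)
  expect_equal(nrow(utils::read.csv(path)), 25)
})
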