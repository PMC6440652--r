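test_that("circuit structure matches the two benchmark topologies", {
  m1 <- unbuf()
  expect_length(m1$state_names, 3)
  expect_length(m1$params, 9)
  expect_length(unbuffered_rhs(c(0, 0, 0), 0), 3)
  m2 <- buf()
  expect_length(m2$state_names, 10)
  expect_length(m2$params, 23)
  expect_length(buffered_rhs(numeric(10), 0), 10)
})

test_that("parameter constraints are enforced at construction", {
  expect_error(circuit_model("unbuffered", params = c(k_on = -1)),
               "non-negative")
  expect_error(circuit_model("buffered", params = c(k1 = 0.5)),
               "\\[1, 50\\]")
  expect_error(circuit_model("buffered", params = c(k1 = 60)),
               "\\[1, 50\\]")
  expect_error(circuit_model("buffered", params = c(k1 = 2, k3 = 5)),
               "k1 >= k3")
  expect_error(circuit_model("buffered", params = c(k2 = 2, k4 = 5)),
               "k2 >= k4")
  expect_error(circuit_model("unbuffered", params = c(bogus = 1)),
               "Unknown kinetic")
})

test_that("zero state with no production is absorbing", {
  expect_equal(unbuffered_rhs(c(0, 0, 0), 0, input = 0,
                              params = circuit_model(
                                "unbuffered",
                                params = c(k_sgfp = 0))$params),
               c(0, 0, 0))
  p <- circuit_model("buffered",
                     params = c(k_w = 0, k_x = 0, k_sgfp = 0,
                                r1 = 0, r2 = 0))$params
  expect_equal(buffered_rhs(numeric(10), 0, params = p, input = 0),
               numeric(10))
})

test_that("unbuffered derivatives match a direct evaluation of the rate laws", {
  p <- default_params("unbuffered")
  k <- default_constants("unbuffered")
  st <- c(Xm = 1, Cm = 0.4, G = 2)
  u <- 20
  # independent re-derivation, written out term by term
  hill_in <- p[["k_m"]] * u^k[["n1"]] / (k[["K_dox"]] + u^k[["n1"]])
  bind <- p[["k_on"]] * st[["Xm"]] * (p[["p_T"]] - st[["Cm"]])
  back <- p[["k_off"]] * st[["Cm"]] + p[["delta_C"]] * st[["Cm"]]
  hill_g <- p[["k_g"]] * st[["Xm"]]^k[["n2"]] /
    (k[["K_gfp"]] + st[["Xm"]]^k[["n2"]])
  expected <- c(hill_in - p[["delta_M"]] * st[["Xm"]] - bind + back,
                bind - back,
                p[["k_sgfp"]] + hill_g - p[["delta_G"]] * st[["G"]])
  expect_equal(unbuffered_rhs(st, 0, input = u), unname(expected),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("buffered derivatives match a direct evaluation of the rate laws", {
  p <- default_params("buffered")
  k <- default_constants("buffered")
  Z <- 0.8; Zs <- 0.3; WT <- 1.2; Ws <- 0.4; XT <- 1.1
  Xs <- 0.2; Xss <- 0.1; Cs <- 0.05; Css <- 0.03; G <- 1.5
  u <- 10
  hill_in <- p[["k_m"]] * u^k[["n1"]] / (k[["K_dox"]] + u^k[["n1"]])
  Xfree <- XT - Xs - Xss - Cs - Css
  Wfree <- WT - Ws
  pfree <- k[["p_T"]] - Cs - Css
  expected <- c(
    hill_in - p[["delta_Z"]] * Z - p[["k2"]] * Ws * Z +
      p[["k1"]] * Zs * Wfree - p[["k_p"]] * Z + p[["k_pp"]] * Zs,
    -p[["k1"]] * Zs * Wfree + p[["k2"]] * Ws * Z + p[["k_p"]] * Z -
      p[["k_pp"]] * Zs - p[["delta_Z"]] * Zs,
    p[["k_w"]] - p[["delta_W"]] * WT,
    p[["k1"]] * Zs * Wfree - p[["k2"]] * Ws * Z -
      p[["k3"]] * Xfree * Ws + p[["k4"]] * Xs * Wfree -
      p[["delta_W"]] * Ws - p[["k3"]] * Xs * Ws +
      p[["k4"]] * Xss * Wfree - p[["k7"]] * Ws,
    p[["k_x"]] - p[["delta_X"]] * XT,
    p[["k3"]] * Xfree * Ws - p[["k4"]] * Xs * Wfree -
      p[["delta_X"]] * Xs - p[["k3"]] * Xs * Ws +
      p[["k4"]] * Xss * Wfree - p[["k5"]] * Xs + p[["k6"]] * Xss +
      p[["r1"]],
    p[["k3"]] * Xs * Ws - p[["k4"]] * Xss * Wfree - p[["k6"]] * Xss -
      p[["delta_X"]] * Xss + p[["r2"]],
    p[["k_on"]] * Xs * pfree - p[["k_off"]] * Cs - p[["delta_C"]] * Cs,
    p[["k_on"]] * Xss * pfree - p[["k_off"]] * Css -
      p[["delta_C"]] * Css,
    p[["k_sgfp"]] + p[["k_g"]] * Xss^k[["n2"]] /
      (k[["K_gfp"]] + Xss^k[["n2"]]) - p[["delta_G"]] * G
  )
  got <- buffered_rhs(c(Z, Zs, WT, Ws, XT, Xs, Xss, Cs, Css, G), 0,
                      input = u)
  expect_equal(got, unname(expected), tolerance = 1e-12)
})

test_that("the integrator-facing derivative agrees with the exported rate laws", {
  set.seed(42)
  u <- make_input("step", 15)
  for (nm in c("unbuffered", "buffered")) {
    m <- circuit_model(nm)
    d <- circuitOED:::make_deriv_fn(m, m$params, u)
    rhs <- circuitOED:::circuit_rhs_fn(m)
    for (r in 1:5) {
      y <- runif(length(m$state_names), 0, 2)
      tt <- runif(1, 0, 200)
      expect_equal(d(tt, y, NULL)[[1]],
                   rhs(y, tt, m$params, m$constants, u, m$load_factor),
                   tolerance = 1e-12)
    }
  }
})

test_that("zero input with no basal production stays at zero", {
  m <- circuit_model("unbuffered", params = c(k_sgfp = 0))
  tr <- simulate_trajectory(m, make_input("step", 0), short_grid())
  expect_true(all(abs(as.matrix(tr[, m$state_names])) < 1e-12))
})

test_that("decoupled GFP decays as a pure exponential", {
  m <- circuit_model("unbuffered", params = c(k_sgfp = 0, k_g = 0))
  tg <- short_grid(300, by = 10)
  tr <- simulate_trajectory(m, make_input("step", 0), tg,
                            y0 = c(Xm = 0, Cm = 0, G = 1))
  expect_equal(tr$G, exp(-m$params[["delta_G"]] * tg), tolerance = 1e-6)
})

test_that("trajectories are non-negative and the complex respects site capacity", {
  for (L in c(1, 2, 3)) {
    m <- circuit_model("unbuffered", load_factor = L)
    tr <- simulate_trajectory(m, make_input("square", 20, period = 200),
                              short_grid(1000, by = 20))
    expect_true(all(as.matrix(tr[, m$state_names]) > -1e-10))
    expect_true(all(tr$Cm <= m$params[["p_T"]] * L + 1e-8))
  }
})

test_that("zero input drives GFP to its basal steady state", {
  m <- unbuf()
  tr <- simulate_trajectory(m, make_input("step", 0), c(0, 1500, 3000))
  target <- m$params[["k_sgfp"]] / m$params[["delta_G"]]
  expect_equal(tr$G[3], target, tolerance = 0.01)
})

test_that("halving the relative tolerance barely moves the GFP trajectory", {
  m <- buf()
  tg <- short_grid(1000, by = 50)
  u <- step20()
  a <- simulate_trajectory(m, u, tg, rtol = 1e-8, atol = 1e-10)
  b <- simulate_trajectory(m, u, tg, rtol = 5e-9, atol = 1e-10)
  expect_lt(max(abs(a$G - b$G)) / max(abs(a$G)), 1e-6)
})

test_that("buffered step response is bounded and settles", {
  m <- buf()
  tr <- simulate_trajectory(m, step20(), seq(0, 3000, by = 50))
  states <- as.matrix(tr[, m$state_names])
  expect_true(all(is.finite(states)))
  expect_true(all(states > -1e-10))
  # re-integration at tighter tolerance confirms the terminal plateau
  tr2 <- simulate_trajectory(m, step20(), seq(0, 3000, by = 50),
                             rtol = 1e-10, atol = 1e-12)
  expect_equal(tr$G[order(tr$time)][61], tr2$G[61], tolerance = 1e-6)
  late <- tr$G[tr$time >= 2500]
  expect_lt(max(late) - min(late), 0.01 * max(tr$G))
})

test_that("trajectory CSV export round-trips", {
  m <- unbuf()
  tr <- simulate_trajectory(m, step20(), short_grid(200, by = 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("time", m$state_names, "input"))
  expect_equal(back$G, tr$G, tolerance = 1e-12)
})

test_that("bad time grids and inputs are rejected", {
  m <- unbuf()
  expect_error(simulate_trajectory(m, step20(), c(1, 2, 3)), "start at 0")
  expect_error(simulate_trajectory(m, step20(), c(0, 2, 2)),
               "strictly increasing")
  expect_error(simulate_trajectory(m, 20, c(0, 1)), "input_signal")
})
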