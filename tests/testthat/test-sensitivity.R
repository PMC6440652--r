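test_that("sensitivities start at exactly zero", {
  S <- forward_sensitivities(unbuf(), step20(), short_grid(200, by = 50),
                             free = c("k_on", "k_off", "k_g"))
  expect_equal(S$values[1, , ], array(0, dim(S$values)[2:3]),
               ignore_attr = TRUE)
  Sb <- forward_sensitivities(buf(), step20(), c(0, 50, 100),
                              free = c("k_on", "k5"))
  expect_equal(max(abs(Sb$values[1, , ])), 0)
})

test_that("states upstream of a parameter have zero sensitivity to it", {
  # k_sgfp, k_g, delta_G enter only the GFP equation, which feeds back
  # into nothing, so Xm and Cm must be flat in them
  S <- forward_sensitivities(unbuf(), step20(), short_grid(400, by = 50),
                             free = c("k_sgfp", "k_g", "delta_G"))
  expect_lt(max(abs(S$values[, c("Xm", "Cm"), ])), 1e-12)
})

test_that("forward sensitivities agree with central finite differences", {
  m <- unbuf()
  tg <- short_grid(400, by = 50)
  free <- c("k_m", "k_on", "k_off", "delta_G")
  Sf <- forward_sensitivities(m, step20(), tg, free = free,
                              rtol = 1e-10, atol = 1e-12)
  Sd <- forward_sensitivities(m, step20(), tg, free = free,
                              method = "finite_diff",
                              rtol = 1e-10, atol = 1e-12)
  expect_lt(sens_rel_diff(Sf, Sd), 1e-3)
})

test_that("rescaling a parameter rescales its sensitivity column by the chain rule", {
  # differentiate with respect to theta = 2 * k_on by finite differences
  # and compare with half the k_on column
  m <- unbuf()
  tg <- short_grid(400, by = 50)
  S <- forward_sensitivities(m, step20(), tg, free = "k_on",
                             rtol = 1e-10, atol = 1e-12)
  theta <- 2 * m$params[["k_on"]]
  # generous step: the response is smooth in theta and a small step would
  # amplify integrator noise relative to this small-magnitude column
  h <- 1e-3 * theta
  y0 <- initial_state(m)
  run <- function(th) {
    p <- m$params; p[["k_on"]] <- th / 2
    simulate_trajectory(m, step20(), tg, params = p, y0 = y0,
                        rtol = 1e-10, atol = 1e-12)$G
  }
  fd_theta <- (run(theta + h) - run(theta - h)) / (2 * h)
  scaled <- S$values[, "G", "k_on"] / 2
  expect_lt(max(abs(fd_theta - scaled)) / max(abs(scaled)), 1e-3)
})

test_that("tidy() flattens the tensor in long format", {
  S <- forward_sensitivities(unbuf(), step20(), c(0, 100, 200),
                             free = c("k_on", "k_off"))
  td <- tidy(S)
  expect_equal(nrow(td), 3 * 3 * 2)
  expect_named(td, c("time", "state", "parameter", "value"))
  expect_equal(td$value[td$time == 200 & td$state == "G" &
                          td$parameter == "k_off"],
               S$values[3, "G", "k_off"])
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity_csv(S, path)
  expect_equal(nrow(utils::read.csv(path)), nrow(td))
})

test_that("Gauss-Newton Hessian equals the cross-product of the flattened matrix", {
  expect_equal(gauss_newton_hessian(diag(3)), diag(3))
  set.seed(1)
  M <- matrix(rnorm(30), 10, 3)
  expect_equal(gauss_newton_hessian(M), t(M) %*% M, tolerance = 1e-12)
  H <- gauss_newton_hessian(M)
  expect_equal(H, t(H))
  expect_gt(min(eigen(H, symmetric = TRUE)$values), -1e-10)
})

test_that("column correlations match the covariance formula and flag degeneracy", {
  set.seed(2)
  M <- matrix(rnorm(80), 20, 4)
  cc <- column_correlation(M)
  # brute-force covariance-based oracle
  oracle <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    oracle[i, j] <- cov(M[, i], M[, j]) / (sd(M[, i]) * sd(M[, j]))
  }
  expect_equal(unname(cc), oracle, tolerance = 1e-12)
  expect_equal(diag(cc), rep(1, 4), ignore_attr = TRUE)
  expect_equal(column_correlation(cbind(a = M[, 1], b = -M[, 1]))[1, 2],
               -1)
  expect_warning(z <- column_correlation(cbind(M[, 1], 0)),
                 "Zero-variance")
  expect_true(is.na(z[1, 2]))
})

test_that("sensitivity tensors reject unknown parameters", {
  expect_error(forward_sensitivities(unbuf(), step20(), c(0, 10),
                                     free = "nope"), "Unknown parameter")
})
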