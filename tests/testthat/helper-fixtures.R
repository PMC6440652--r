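# Shared fixtures: small, fast experiment settings used across tests.

step20 <- function() make_input("step", magnitude = 20)

unbuf <- function(...) circuit_model("unbuffered", ...)
buf <- function(...) circuit_model("buffered", ...)

short_grid <- function(t_f = 600, by = 24) seq(0, t_f, by = by)

noiseless <- function() noise_model(sigma_rel = 0, sigma_floor = 0)

# Max relative deviation between two sensitivity tensors, scaled per
# parameter by the largest magnitude that parameter attains in `ref`
# (with a floor so pure-noise columns of a numerically zero sensitivity
# do not inflate the ratio).
sens_rel_diff <- function(x, ref, floor = 1e-8) {
  worst <- 0
  for (j in seq_along(ref$param_names)) {
    sc <- max(abs(ref$values[, , j]), floor)
    worst <- max(worst, max(abs(x$values[, , j] - ref$values[, , j])) / sc)
  }
  worst
}
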