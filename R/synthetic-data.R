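# Synthetic noisy measurements ------------------------------------------
#
# Stand-in for wet-lab fluorescence data: the circuit is simulated, the
# GFP observable is sampled at chosen times and independent Gaussian noise
# with sigma_i = max(sigma_rel * |y_i|, sigma_floor) is added.  The
# sigma_i actually used are recorded in the output and are the single
# source of truth for downstream wRSSE weighting and FIM construction.

#' Default measurement-noise settings
#'
#' Repository defaults (the original study does not state its noise
#' magnitudes): 5% relative noise with an absolute floor of 1e-3 uM.
#'
#' @param sigma_rel Relative noise level (fraction of the signal).
#' @param sigma_floor Absolute noise floor (uM).
#' @param clip Clip negative noisy values to zero?  Default `FALSE` so the
#'   Gaussian noise assumption (and chi-squared GOF calibration) holds
#'   exactly; set `TRUE` for realism.
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma_rel = 0.05, sigma_floor = 1e-3,
                        clip = FALSE) {
  if (sigma_rel < 0 || sigma_floor < 0) {
    stop("Noise parameters must be non-negative.", call. = FALSE)
  }
  structure(list(sigma_rel = sigma_rel, sigma_floor = sigma_floor,
                 clip = clip),
            class = "noise_model")
}

#' Generate noisy sampled measurements from a circuit
#'
#' Simulates the model under `input`, samples the GFP observable at `n_m`
#' evenly spaced times over `[0, t_f]` (or at explicit `times`), and adds
#' independent Gaussian noise per the noise model.  With
#' `sigma_rel = sigma_floor = 0` the exact noiseless samples are returned
#' with `std = 0`.
#'
#' @param model A [circuit_model()].
#' @param input An [input_signal][make_input].
#' @param n_m Number of measured time points (>= 2).
#' @param t_f Experiment duration (min); default 3000.
#' @param times Explicit sampling times overriding `n_m`/`t_f`.
#' @param params True kinetic vector used for simulation.
#' @param noise A [noise_model()].
#' @param seed Integer seed making the draw reproducible.
#' @param replicates Number of independent noise replicates per time point
#'   (default 1); replicates share the noiseless trajectory.
#' @return A tibble of class `measurement_set` with columns `time`,
#'   `value`, `std` (and `replicate` when `replicates > 1`); the noiseless
#'   truth, seed and descriptors are attached as attributes.
#' @examples
#' mod <- circuit_model("unbuffered")
#' m <- generate_measurements(mod, make_input("step", 20), n_m = 10,
#'                            t_f = 600, seed = 1)
#' m
#' @export
generate_measurements <- function(model, input, n_m = 50, t_f = 3000,
                                  times = NULL, params = model$params,
                                  noise = noise_model(), seed = 1L,
                                  replicates = 1L) {
  stopifnot(inherits(model, "circuit_model"))
  if (is.null(times)) {
    if (n_m < 2) stop("`n_m` must be at least 2.", call. = FALSE)
    times <- seq(0, t_f, length.out = n_m)
  } else {
    times <- as.numeric(times)
    if (any(diff(times) <= 0) || times[1] < 0) {
      stop("`times` must be strictly increasing and non-negative.",
           call. = FALSE)
    }
  }
  grid <- sort(unique(c(0, times)))
  tr <- simulate_trajectory(model, input, grid, params = params)
  truth <- tr$G[match(times, tr$time)]
  sample_measurements(truth, times, noise = noise, seed = seed,
                      replicates = replicates, input = input)
}

#' Add measurement noise to noiseless observable samples
#'
#' The noise layer of [generate_measurements()], exposed separately so
#' replicate draws can reuse one simulated trajectory.
#'
#' @param truth Noiseless observable values at `times`.
#' @param times Sampling times (min).
#' @inheritParams generate_measurements
#' @param input Optional input descriptor attached to the result.
#' @return A `measurement_set` tibble (see [generate_measurements()]).
#' @export
sample_measurements <- function(truth, times, noise = noise_model(),
                                seed = 1L, replicates = 1L, input = NULL) {
  stds <- pmax(noise$sigma_rel * abs(truth), noise$sigma_floor)
  n <- length(truth)
  eps <- with_seed(seed, stats::rnorm(n * replicates)) *
    rep(stds, replicates)
  values <- rep(truth, replicates) + eps
  if (noise$clip) values <- pmax(values, 0)
  out <- tibble::tibble(
    time = rep(times, replicates),
    value = values,
    std = rep(stds, replicates)
  )
  if (replicates > 1L) {
    out$replicate <- rep(seq_len(replicates), each = n)
  }
  structure(out, class = c("measurement_set", class(out)),
            truth = rep(truth, replicates), observable = "G",
            input = input, noise = noise, seed = as.integer(seed))
}

#' Write / read a measurement set as CSV
#'
#' Columns `time`, `value`, `std` (and `replicate` if present), written at
#' full double precision (repr-level round trip).
#'
#' @param x A `measurement_set`.
#' @param path File path.
#' @return `path` invisibly (write); a `measurement_set` tibble (read).
#' @export
write_measurements_csv <- function(x, path) {
  df <- as.data.frame(x)
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- sprintf("%.17g", df[[col]])
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("time", "value", "std")
  if (!all(need %in% names(df))) {
    stop("Measurement CSV must have columns time, value, std.",
         call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  structure(out, class = c("measurement_set", class(out)))
}
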