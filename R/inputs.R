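#' Construct a deterministic induction signal
#'
#' Builds the time-dependent doxorubicin (DOX) input \eqn{u(t)} applied to a
#' gene circuit.  Four waveforms are supported:
#'
#' * `"constant"`: \eqn{u(t) = } `magnitude` for all \eqn{t \ge 0}.
#' * `"step"`: 0 before `onset`, `magnitude` afterwards.
#' * `"double_step"`: a step of `magnitude` at `onset`, then a second step to
#'   `second_magnitude` at `second_onset`.
#' * `"square"`: a square wave of amplitude `magnitude` and period `period`
#'   with 50% duty cycle, high phase first: high on
#'   \eqn{[kT, kT + T/2)}, zero otherwise.
#'
#' @param kind One of `"constant"`, `"step"`, `"double_step"`, `"square"`.
#' @param magnitude Signal level in uM; must be non-negative.
#' @param onset Switch-on time in minutes (default 0).
#' @param period Period in minutes, required for `kind = "square"`.
#' @param second_onset,second_magnitude Second plateau for
#'   `kind = "double_step"`; `second_onset` must exceed `onset`.
#'
#' @return An object of class `input_signal`.  Evaluate it with
#'   [input_value()] or coerce it to a plain function with `as.function()`.
#' @examples
#' u <- make_input("square", magnitude = 20, period = 100)
#' input_value(u, c(25, 75))
#' @export
make_input <- function(kind = c("step", "double_step", "square", "constant"),
                       magnitude, onset = 0, period = NULL,
                       second_onset = NULL, second_magnitude = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(magnitude) || length(magnitude) != 1L || is.na(magnitude) ||
      magnitude < 0) {
    stop("`magnitude` must be a single non-negative number (uM).",
         call. = FALSE)
  }
  if (!is.numeric(onset) || length(onset) != 1L || onset < 0) {
    stop("`onset` must be a single non-negative time (min).", call. = FALSE)
  }
  if (kind == "square") {
    if (is.null(period) || !is.numeric(period) || length(period) != 1L ||
        is.na(period) || period <= 0) {
      stop("`period` must be a positive number of minutes for a square wave.",
           call. = FALSE)
    }
  }
  if (kind == "double_step") {
    if (is.null(second_onset) || is.null(second_magnitude)) {
      stop("double_step requires `second_onset` and `second_magnitude`.",
           call. = FALSE)
    }
    if (second_onset <= onset) {
      stop("`second_onset` must be later than `onset`.", call. = FALSE)
    }
    if (second_magnitude < 0) {
      stop("`second_magnitude` must be non-negative.", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, magnitude = magnitude, onset = onset,
         period = period, second_onset = second_onset,
         second_magnitude = second_magnitude),
    class = "input_signal"
  )
}

#' Evaluate an induction signal
#'
#' @param signal An [input_signal][make_input] object.
#' @param t Numeric vector of times (min).
#' @return Numeric vector of signal values (uM), same length as `t`.
#' @export
input_value <- function(signal, t) {
  stopifnot(inherits(signal, "input_signal"))
  t <- as.numeric(t)
  out <- switch(
    signal$kind,
    constant = rep(signal$magnitude, length(t)),
    step = ifelse(t >= signal$onset, signal$magnitude, 0),
    double_step = ifelse(
      t >= signal$second_onset, signal$second_magnitude,
      ifelse(t >= signal$onset, signal$magnitude, 0)
    ),
    square = {
      phase <- (t - signal$onset) %% signal$period
      ifelse(t >= signal$onset & phase < signal$period / 2,
             signal$magnitude, 0)
    }
  )
  out
}

#' @export
as.function.input_signal <- function(x, ...) {
  force(x)
  function(t) input_value(x, t)
}

#' @export
print.input_signal <- function(x, ...) {
  cat("<input_signal> kind:", x$kind, " magnitude:", x$magnitude, "uM")
  if (!is.null(x$period)) cat("  period:", x$period, "min")
  if (x$onset > 0) cat("  onset:", x$onset, "min")
  if (!is.null(x$second_onset)) {
    cat("  then", x$second_magnitude, "uM at", x$second_onset, "min")
  }
  cat("\n")
  invisible(x)
}

# Times in [0, t_max] where the signal is discontinuous; the integrator is
# restarted at each of these so square/step edges are resolved exactly.
input_breaks <- function(signal, t_max) {
  br <- switch(
    signal$kind,
    constant = numeric(0),
    step = signal$onset,
    double_step = c(signal$onset, signal$second_onset),
    square = {
      half <- signal$period / 2
      edges <- seq(signal$onset, t_max, by = half)
      edges
    }
  )
  br <- br[br > 0 & br < t_max]
  sort(unique(br))
}
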