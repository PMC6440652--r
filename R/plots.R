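# autoplot methods --------------------------------------------------------

#' Plot a simulated trajectory
#'
#' All states (faceted, free scales) with the input level overlaid on its
#' own facet.
#'
#' @param object A [simulate_trajectory()] result.
#' @param states Optional subset of state names to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circuit_trajectory <- function(object, states = NULL, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(df, -"time", names_to = "series",
                              values_to = "value")
  if (!is.null(states)) {
    long <- dplyr::filter(long, .data$series %in% c(states, "input"))
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (uM)") +
    ggplot2::theme_minimal()
}

#' Plot a measurement set over its noiseless truth
#'
#' @param object A [generate_measurements()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.measurement_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  truth <- attr(object, "truth")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$value - .data$std,
                   ymax = .data$value + .data$std),
      size = 0.2, color = "#636363"
    ) +
    ggplot2::labs(x = "time (min)", y = "GFP (uM)") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(time = df$time, value = truth),
      color = "#2c7fb8"
    )
  }
  p
}

#' Plot sensitivity trajectories of the observable
#'
#' @param object A [forward_sensitivities()] result.
#' @param observable State name to show (default the GFP observable).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_tensor <- function(object, observable = NULL, ...) {
  obs <- observable %||% object$state_names[object$observable]
  long <- dplyr::filter(tidy.sensitivity_tensor(object),
                        .data$state == obs)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     color = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "time (min)",
                  y = paste0("d ", obs, " / d parameter")) +
    ggplot2::theme_minimal()
}

#' Plot per-parameter Cramer-Rao bounds
#'
#' @param object A [fisher_information()] result.
#' @param ... Unused.
#' @return A ggplot object (log-scale bars of the variance bounds).
#' @export
autoplot.fim_result <- function(object, ...) {
  df <- tidy.fim_result(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$crlb)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "CRLB (variance)") +
    ggplot2::theme_minimal()
}

#' Plot an optimizer fitness trace
#'
#' @param object An `opt_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.opt_result <- function(object, ...) {
  ggplot2::ggplot(tidy.opt_result(object),
                  ggplot2::aes(.data$iteration, .data$best_fitness)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "iteration", y = "incumbent best fitness",
                  title = object$method) +
    ggplot2::theme_minimal()
}

#' Plot the candidate input levels of a nested design run
#'
#' @param object An [outer_design()] result.
#' @param ... Unused.
#' @return A ggplot object: criterion against candidate u, the selected
#'   level marked.
#' @export
autoplot.oed_result <- function(object, ...) {
  df <- object$evaluations
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$criterion)) +
    ggplot2::geom_point(color = "#636363") +
    ggplot2::geom_vline(xintercept = object$u_star, color = "#de2d26",
                        linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "input level u (uM)",
                  y = "design criterion (modE)") +
    ggplot2::theme_minimal()
}

#' Plot a sample-size cost curve
#'
#' @param object A [select_sample_size()] result.
#' @param ... Unused.
#' @return A ggplot object with the selected sample size marked.
#' @export
autoplot.sample_size_result <- function(object, ...) {
  df <- object$cost_curve
  ggplot2::ggplot(df, ggplot2::aes(.data$n_m, .data$J)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_m_star, color = "#de2d26",
                        linetype = 2) +
    ggplot2::labs(x = "number of measured time points",
                  y = "cost J(n_m)") +
    ggplot2::theme_minimal()
}

#' Plot a steady-state dose-response table
#'
#' @param object A [dose_response()] tibble.
#' @param ... Unused.
#' @return A ggplot object: steady GFP and gain against DOX (log x).
#' @export
autoplot.dose_response <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("steady_gfp", "gain"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$dox, .data$value)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "DOX (uM)", y = NULL) +
    ggplot2::theme_minimal()
}
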