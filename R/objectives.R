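# Error indexes, measurement-cost objective, goodness of fit ------------

#' Root-mean-square error
#'
#' @param y,yhat Equal-length numeric vectors of measured and predicted
#'   values.
#' @return \eqn{\sqrt{\frac{1}{n}\sum_i (y_i - \hat y_i)^2}}.
#' @examples
#' rmse(c(3, 4), c(0, 0))
#' @export
rmse <- function(y, yhat) {
  check_same_length(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' Weighted residual sum of squared errors (wRSSE)
#'
#' Residuals scaled by the per-point measurement standard deviations:
#' \eqn{\phi(p) = \sum_k ((y_k - \hat y_k)/\sigma_k)^2}.  With known
#' Gaussian noise this statistic follows a chi-squared distribution, which
#' [gof_chi2()] exploits.
#'
#' @inheritParams rmse
#' @param sigma Positive standard deviations (recycled if scalar).
#' @return Non-negative scalar.
#' @examples
#' wrsse(2, 0, sigma = 2)
#' @export
wrsse <- function(y, yhat, sigma = 1) {
  check_same_length(y, yhat)
  if (length(sigma) == 1L) sigma <- rep(sigma, length(y))
  if (length(sigma) != length(y)) {
    stop("`sigma` must be scalar or match the data length.", call. = FALSE)
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("All `sigma` must be positive.", call. = FALSE)
  }
  sum(((y - yhat) / sigma)^2)
}

check_same_length <- function(y, yhat) {
  if (length(y) == 0L) stop("Empty input.", call. = FALSE)
  if (length(y) != length(yhat)) {
    stop("`y` and `yhat` must have the same length.", call. = FALSE)
  }
  invisible(TRUE)
}

#' Accuracy-vs-measurement-cost objective for sample-size selection
#'
#' The cost of measuring `n_m` time points when fitting `n_p` parameters:
#' \deqn{J(n_m) = \sum_i (y_i - \hat y_i)^2 + \lambda (n_m - n_p)/n_m,}
#' a residual-accuracy term plus a normalized measurement-cost penalty
#' motivated by the chi-squared degrees of freedom.  The penalty increases
#' towards \eqn{\lambda} as \eqn{n_m} grows, so past a point extra samples
#' cost more than they improve the fit.  Setting `weighted = TRUE` replaces
#' the raw residual sum with the sigma-weighted [wrsse()] (an alternative
#' reading of the accuracy term; the raw sum is the default).
#'
#' @param residuals Numeric vector of residuals \eqn{y_i - \hat y_i} at the
#'   `n_m` measured points.
#' @param n_m Number of measured time points; must exceed `n_p`.
#' @param n_p Number of estimated parameters (>= 1).
#' @param lambda Non-negative penalty coefficient (default 0.8).
#' @param sigma Standard deviations used when `weighted = TRUE`.
#' @param weighted Use the weighted residual sum (default `FALSE`).
#' @return List with `J`, `accuracy` (the residual term) and `penalty`
#'   (\eqn{(n_m - n_p)/n_m}, before multiplying by `lambda`).
#' @examples
#' sample_size_cost(numeric(50), n_m = 50, n_p = 23)$penalty  # 0.54
#' @export
sample_size_cost <- function(residuals, n_m, n_p, lambda = 0.8,
                             sigma = 1, weighted = FALSE) {
  if (n_p < 1) stop("`n_p` must be at least 1.", call. = FALSE)
  if (n_m <= n_p) {
    stop("`n_m` must exceed the number of estimated parameters `n_p`.",
         call. = FALSE)
  }
  if (lambda < 0) stop("`lambda` must be non-negative.", call. = FALSE)
  acc <- if (weighted) {
    wrsse(residuals, numeric(length(residuals)), sigma)
  } else {
    sum(residuals^2)
  }
  penalty <- (n_m - n_p) / n_m
  list(J = acc + lambda * penalty, accuracy = acc, penalty = penalty)
}

#' Chi-squared goodness of fit for a weighted residual sum
#'
#' With known Gaussian measurement noise, the wRSSE statistic
#' \eqn{\phi(p)} follows a chi-squared distribution with
#' `r = n_data - n_params` degrees of freedom under the true model; the
#' upper-tail probability is the GOF p-value.
#'
#' @param phi A [wrsse()] value.
#' @param n_data Number of data points.
#' @param n_params Number of estimated parameters; must be < `n_data`.
#' @return List with `dof` and `p_value`.
#' @examples
#' gof_chi2(27, n_data = 50, n_params = 23)
#' @export
gof_chi2 <- function(phi, n_data, n_params) {
  dof <- n_data - n_params
  if (dof < 1) {
    stop("Degrees of freedom must be positive (n_data > n_params).",
         call. = FALSE)
  }
  if (phi < 0) stop("`phi` must be non-negative.", call. = FALSE)
  list(dof = dof, p_value = stats::pchisq(phi, df = dof, lower.tail = FALSE))
}

#' Normal quantile-quantile pairs for residual diagnostics
#'
#' Sorted residuals paired with standard-normal quantiles at plotting
#' positions \eqn{(i - 0.5)/n}.  Approximately normal residuals fall on a
#' straight line.
#'
#' @param residuals Numeric vector, length >= 3.
#' @return Tibble with columns `theoretical` and `sample`, both ascending.
#' @examples
#' qq_points(c(-1, 0, 1))
#' @export
qq_points <- function(residuals) {
  n <- length(residuals)
  if (n < 3) stop("Need at least 3 residuals.", call. = FALSE)
  tibble::tibble(
    theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
    sample = sort(residuals)
  )
}

#' Fit diagnostics for a measurement set against model predictions
#'
#' Convenience wrapper combining [rmse()], [wrsse()], [gof_chi2()] and
#' [qq_points()] for one fitted model.
#'
#' @param y,yhat Measured and predicted values.
#' @param sigma Measurement standard deviations.
#' @param n_params Number of estimated parameters.
#' @return A `fit_diagnostics` list: `rmse`, `wrsse`, `residuals`, `dof`,
#'   `chi2_pvalue`, `qq` (tibble).
#' @export
fit_diagnostics <- function(y, yhat, sigma, n_params) {
  res <- y - yhat
  phi <- wrsse(y, yhat, sigma)
  gof <- gof_chi2(phi, length(y), n_params)
  structure(
    list(rmse = rmse(y, yhat), wrsse = phi, residuals = res,
         dof = gof$dof, chi2_pvalue = gof$p_value,
         qq = if (length(res) >= 3) qq_points(res) else NULL),
    class = "fit_diagnostics"
  )
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat("<fit_diagnostics> RMSE =", format(x$rmse, digits = 4),
      " wRSSE =", format(x$wrsse, digits = 4),
      " dof =", x$dof,
      " chi2 p =", format(x$chi2_pvalue, digits = 3), "\n")
  invisible(x)
}

#' @export
glance.fit_diagnostics <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, wrsse = x$wrsse, dof = x$dof,
                 chi2_pvalue = x$chi2_pvalue, n = length(x$residuals))
}
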