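# Fisher information and optimality criteria ----------------------------

#' Fisher information matrix from sensitivities
#'
#' Builds \eqn{F = \sum_i S(t_i)^T \mathrm{diag}(1/\sigma_i^2) S(t_i)} over
#' the measured time points, where the rows of S are the sensitivities of
#' the observed state(s) and \eqn{\sigma_i} the per-point measurement
#' standard deviations.  Under Gaussian noise the inverse of F lower-bounds
#' the covariance of any unbiased estimator (Cramer-Rao), so eigen-analysis
#' of F quantifies how well a design constrains the parameters.
#'
#' @param S A [forward_sensitivities()] result, or a numeric matrix
#'   (observations x parameters).
#' @param sigmas Positive standard deviations, one per observation row
#'   (recycled if scalar).
#' @param observable State index/indices to observe when `S` is a tensor;
#'   defaults to the GFP state.
#' @return A `fim_result`: list with the symmetrized matrix `F`,
#'   `eigenvalues` (decreasing), per-parameter `crlb` (diagonal of the
#'   inverse), `criteria` (A, D, E, modE), and a `singular` flag.
#' @examples
#' fisher_information(diag(2), sigmas = 1)
#' @export
fisher_information <- function(S, sigmas, observable = NULL) {
  M <- if (inherits(S, "sensitivity_tensor")) {
    obs <- observable %||% S$observable
    do.call(rbind, lapply(obs, function(i) observable_sensitivities(S, i)))
  } else {
    as.matrix(S)
  }
  sigmas <- as.numeric(sigmas)
  if (length(sigmas) == 1L) sigmas <- rep(sigmas, nrow(M))
  if (length(sigmas) != nrow(M)) {
    stop("`sigmas` must have one entry per observation row.", call. = FALSE)
  }
  if (any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    stop("All measurement standard deviations must be positive.",
         call. = FALSE)
  }
  FM <- crossprod(M / sigmas)
  FM <- (FM + t(FM)) / 2
  new_fim_result(FM, colnames(M))
}

new_fim_result <- function(FM, param_names = colnames(FM),
                           singular_tol = 1e-12) {
  ev <- eigen(FM, symmetric = TRUE, only.values = FALSE)
  lam <- ev$values
  singular <- lam[1] <= 0 || min(lam) / lam[1] < singular_tol
  crlb <- crlb_from_eigen(ev, singular_tol)
  names(crlb) <- param_names
  criteria <- c(
    A = if (singular) Inf else sum(1 / lam),
    D = prod(lam),
    E = min(lam),
    modE = if (singular) Inf else lam[1] / min(lam)
  )
  structure(
    list(F = FM, eigenvalues = lam, crlb = crlb, criteria = criteria,
         singular = singular, param_names = param_names),
    class = "fim_result"
  )
}

crlb_from_eigen <- function(ev, singular_tol = 1e-12) {
  lam <- ev$values
  V <- ev$vectors
  keep <- lam > singular_tol * max(lam[1], 0)
  n <- length(lam)
  out <- numeric(n)
  for (j in seq_len(n)) {
    null_mass <- sum(V[j, !keep]^2)
    out[j] <- if (null_mass > 1e-10) {
      Inf  # parameter aligned with a null direction: unidentifiable
    } else {
      sum(V[j, keep]^2 / lam[keep])
    }
  }
  out
}

#' Cramer-Rao lower bounds from a Fisher matrix
#'
#' Per-parameter variance lower bounds: the diagonal of \eqn{F^{-1}}.  If F
#' is numerically singular (smallest/largest eigenvalue below 1e-12) the
#' bound is reported as `Inf` for parameters aligned with the null space
#' and a non-identifiability warning is raised.
#'
#' @param F A `fim_result` or a symmetric numeric matrix.
#' @return Numeric vector of variance bounds (> 0, possibly `Inf`).
#' @examples
#' crlb(diag(c(4, 1)))
#' @export
crlb <- function(F) {
  res <- if (inherits(F, "fim_result")) F else new_fim_result(as.matrix(F))
  if (res$singular) {
    warning("Fisher matrix is numerically singular: some parameters are ",
            "practically unidentifiable (infinite bounds).", call. = FALSE)
  }
  res$crlb
}

#' Scalar design criteria of a Fisher matrix
#'
#' * `A`: trace of the inverse (average variance; minimize).
#' * `D`: determinant (information volume; maximize).
#' * `E`: smallest eigenvalue (worst-constrained direction; maximize).
#' * `modE`: condition number \eqn{\lambda_{max}/\lambda_{min}} (balance of
#'   information; minimize, with 1 the ideal).
#'
#' `modE` and `A` are reported `Inf` for a singular F.
#'
#' @inheritParams crlb
#' @param kind One of `"A"`, `"D"`, `"E"`, `"modE"`.
#' @return A single numeric value.
#' @examples
#' scalar_criterion(diag(c(4, 1)), "modE")
#' @export
scalar_criterion <- function(F, kind = c("modE", "A", "D", "E")) {
  kind <- match.arg(kind)
  res <- if (inherits(F, "fim_result")) F else new_fim_result(as.matrix(F))
  unname(res$criteria[kind])
}

#' @export
print.fim_result <- function(x, ...) {
  cat("<fim_result>", nrow(x$F), "parameters; modE =",
      format(x$criteria[["modE"]], digits = 4),
      if (x$singular) "(singular)" else "", "\n")
  invisible(x)
}

#' Tidy per-parameter view of a Fisher matrix
#'
#' @param x A `fim_result`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `crlb` (variance bound) and `crlb_sd`
#'   (its square root).
#' @export
tidy.fim_result <- function(x, ...) {
  tibble::tibble(
    parameter = x$param_names %||% paste0("p", seq_along(x$crlb)),
    crlb = unname(x$crlb),
    crlb_sd = sqrt(unname(x$crlb))
  )
}

#' One-row summary of a Fisher matrix
#'
#' @inheritParams tidy.fim_result
#' @return Tibble with the four criteria, the extreme eigenvalues and the
#'   singularity flag.
#' @export
glance.fim_result <- function(x, ...) {
  tibble::tibble(
    A = x$criteria[["A"]], D = x$criteria[["D"]],
    E = x$criteria[["E"]], modE = x$criteria[["modE"]],
    lambda_max = x$eigenvalues[1],
    lambda_min = min(x$eigenvalues),
    singular = x$singular
  )
}

#' Serialize a Fisher-information report
#'
#' Writes the matrix, eigenvalues, criteria and per-parameter CRLB table
#' as pretty JSON.
#'
#' @param x A `fim_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fim_report <- function(x, path) {
  rep <- list(
    parameters = x$param_names,
    fisher_matrix = unname(apply(x$F, 1, as.numeric, simplify = FALSE)),
    eigenvalues = x$eigenvalues,
    criteria = as.list(x$criteria),
    crlb = as.list(x$crlb),
    singular = x$singular
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
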