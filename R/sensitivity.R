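# Forward sensitivity analysis ------------------------------------------
#
# Local sensitivities s(t) = dx(t)/dp are integrated alongside the states
# via the forward sensitivity equations
#     ds/dt = Jx(t, p0) s + Jp(t, p0),  s(0) = 0,
# where Jx = df/dx and Jp = df/dp are obtained by symbolic differentiation
# (stats::D) of the circuit RHS expression lists, so the Jacobians are
# closed-form.  A central finite-difference fallback serves as an
# independent route.  The initial state is treated as a fixed experimental
# condition (evaluated at the reference parameters), so S(0) = 0 exactly
# for both routes.

.jac_cache <- new.env(parent = emptyenv())

# Expression matrix of derivatives d exprs[i] / d vars[j], compiled into a
# single evaluator returning the numeric matrix.
build_jacobian_eval <- function(exprs, vars) {
  nr <- length(exprs); nc <- length(vars)
  cells <- character(nr * nc)
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      d <- stats::D(exprs[[i]], vars[j])
      cells[(j - 1L) * nr + i] <- paste(deparse(d), collapse = " ")
    }
  }
  txt <- paste0("matrix(c(", paste(cells, collapse = ",\n"), "), ",
                nr, "L, ", nc, "L)")
  ex <- parse(text = txt)[[1]]
  function(env) eval(ex, env)
}

circuit_jacobians <- function(name) {
  key <- name
  if (!is.null(.jac_cache[[key]])) return(.jac_cache[[key]])
  spec <- circuit_spec(name)
  jac <- list(
    jx = build_jacobian_eval(spec$exprs, spec$states),
    jp = build_jacobian_eval(spec$exprs, spec$params),
    param_names = spec$params
  )
  .jac_cache[[key]] <- jac
  jac
}

rhs_env <- function(state, model, params, u) {
  c(as.list(state), as.list(params), as.list(model$constants),
    list(u = u, L = model$load_factor))
}

#' Forward parameter sensitivities of a circuit
#'
#' Computes the sensitivity tensor \eqn{s_{ij}(t_k) = \partial x_i(t_k) /
#' \partial p_j} either by integrating the forward sensitivity ODEs with
#' closed-form Jacobians (`method = "forward_ode"`) or by central finite
#' differences on the trajectory (`method = "finite_diff"`, relative step
#' 1e-5 with absolute floor 1e-8).  The initial state is held fixed at its
#' reference-parameter value, so all sensitivities vanish at t = 0.
#'
#' @param model A [circuit_model()].
#' @param input An [input_signal][make_input].
#' @param time_grid Strictly increasing output times starting at 0 (min).
#' @param params Reference kinetic vector (default `model$params`).
#' @param free Character vector of parameter names to differentiate
#'   against (default all kinetic parameters).
#' @param method `"forward_ode"` (default) or `"finite_diff"`.
#' @param rtol,atol Solver tolerances.
#' @param rel_step,abs_floor Finite-difference step control.
#' @return A `sensitivity_tensor`: list with `time_grid`, `values` (array
#'   n_t x n_states x n_params), `state_names`, `param_names`, `params`,
#'   `observable`.
#' @examples
#' mod <- circuit_model("unbuffered")
#' S <- forward_sensitivities(mod, make_input("step", 20),
#'                            seq(0, 200, by = 20),
#'                            free = c("k_on", "k_off"))
#' dim(S$values)
#' @export
forward_sensitivities <- function(model, input, time_grid,
                                  params = model$params,
                                  free = model$param_names,
                                  method = c("forward_ode", "finite_diff"),
                                  rtol = 1e-8, atol = 1e-10,
                                  rel_step = 1e-5, abs_floor = 1e-8) {
  stopifnot(inherits(model, "circuit_model"))
  method <- match.arg(method)
  params <- params[model$param_names]
  bad <- setdiff(free, model$param_names)
  if (length(bad)) {
    stop("Unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  time_grid <- as.numeric(time_grid)
  vals <- if (method == "forward_ode") {
    sens_forward_ode(model, input, time_grid, params, free, rtol, atol)
  } else {
    sens_finite_diff(model, input, time_grid, params, free, rtol, atol,
                     rel_step, abs_floor)
  }
  structure(
    list(time_grid = time_grid, values = vals,
         state_names = model$state_names, param_names = free,
         params = params, observable = model$observable,
         method = method, model_name = model$name),
    class = "sensitivity_tensor"
  )
}

sens_forward_ode <- function(model, input, time_grid, params, free,
                             rtol, atol) {
  ns <- length(model$state_names)
  np <- length(free)
  jac <- circuit_jacobians(model$name)
  free_idx <- match(free, jac$param_names)
  state_deriv <- make_deriv_fn(model, params, input)
  base_env <- c(as.list(params), as.list(model$constants),
                list(L = model$load_factor))
  y0 <- c(initial_state(model, params), numeric(ns * np))
  state_idx <- seq_len(ns)
  snames <- model$state_names
  deriv <- function(t, y, parms) {
    state <- y[state_idx]
    S <- matrix(y[-state_idx], ns, np)
    env <- base_env
    env[snames] <- state
    env$u <- input_value(input, t)
    Jx <- jac$jx(env)
    Jp <- jac$jp(env)[, free_idx, drop = FALSE]
    dx <- state_deriv(t, state, NULL)[[1]]
    list(c(dx, as.vector(Jx %*% S + Jp)))
  }
  sol <- integrate_piecewise(deriv, y0, time_grid, input, rtol, atol)
  n_t <- nrow(sol)
  arr <- array(sol[, -seq_len(ns + 1L), drop = FALSE],
               dim = c(n_t, ns, np),
               dimnames = list(NULL, model$state_names, free))
  if (any(!is.finite(arr))) {
    stop("Sensitivity integration produced non-finite values.",
         call. = FALSE)
  }
  arr
}

sens_finite_diff <- function(model, input, time_grid, params, free,
                             rtol, atol, rel_step, abs_floor) {
  ns <- length(model$state_names)
  np <- length(free)
  y0 <- initial_state(model, params)
  run <- function(p) {
    tr <- simulate_trajectory(model, input, time_grid, params = p,
                              y0 = y0, rtol = rtol, atol = atol)
    as.matrix(as.data.frame(tr)[, model$state_names, drop = FALSE])
  }
  arr <- array(NA_real_, dim = c(length(time_grid), ns, np),
               dimnames = list(NULL, model$state_names, free))
  for (j in seq_len(np)) {
    pj <- params[[free[j]]]
    h <- max(rel_step * abs(pj), abs_floor)
    if (h <= 0) stop("Finite-difference step underflow.", call. = FALSE)
    up <- params; up[[free[j]]] <- pj + h
    dn <- params; dn[[free[j]]] <- pj - h
    if (dn[[free[j]]] < 0) dn[[free[j]]] <- 0  # keep parameters feasible
    denom <- up[[free[j]]] - dn[[free[j]]]
    arr[, , j] <- (run(up) - run(dn)) / denom
  }
  arr
}

#' Tidy a sensitivity tensor into long format
#'
#' @param x A [forward_sensitivities()] result.
#' @param ... Unused.
#' @return Tibble with columns `time`, `state`, `parameter`, `value`.
#' @export
tidy.sensitivity_tensor <- function(x, ...) {
  grid <- expand.grid(time = x$time_grid, state = x$state_names,
                      parameter = x$param_names,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$value <- as.vector(x$values)
  tibble::as_tibble(grid)
}

#' @export
print.sensitivity_tensor <- function(x, ...) {
  cat("<sensitivity_tensor>", x$model_name, "circuit:",
      length(x$time_grid), "times x", length(x$state_names), "states x",
      length(x$param_names), "parameters (", x$method, ")\n")
  invisible(x)
}

#' Write sensitivities as long-format CSV
#'
#' @inheritParams tidy.sensitivity_tensor
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(x, path) {
  utils::write.csv(as.data.frame(tidy.sensitivity_tensor(x)), path,
                   row.names = FALSE)
  invisible(path)
}

# Rows of the flattened observable-sensitivity matrix: n_t x n_params.
observable_sensitivities <- function(S, observable = S$observable) {
  m <- S$values[, observable, , drop = FALSE]
  matrix(m, dim(S$values)[1], dim(S$values)[3],
         dimnames = list(NULL, S$param_names))
}

#' Gauss-Newton Hessian from a sensitivity tensor
#'
#' The Gauss-Newton approximation of the least-squares Hessian,
#' \eqn{H = S^T S}, where the rows of S are the sensitivities of the
#' observed state(s) at each time point.  H is symmetric positive
#' semi-definite by construction.
#'
#' @param S A [forward_sensitivities()] result, or a plain numeric matrix
#'   (observations x parameters).
#' @param observable State index (default: the GFP state of the tensor).
#' @return Symmetric numeric matrix (n_params x n_params).
#' @export
gauss_newton_hessian <- function(S, observable = NULL) {
  M <- if (inherits(S, "sensitivity_tensor")) {
    observable_sensitivities(S, observable %||% S$observable)
  } else {
    as.matrix(S)
  }
  H <- crossprod(M)
  (H + t(H)) / 2
}

#' Pairwise correlation of sensitivity columns
#'
#' Correlations between columns of the flattened sensitivity matrix
#' diagnose practical non-identifiability: |corr| = 1 means two parameters
#' move the observable along linearly dependent directions.  Columns with
#' zero variance give `NA` entries (flagged with a warning), never a
#' silent 0.
#'
#' @inheritParams gauss_newton_hessian
#' @return Symmetric correlation matrix with unit diagonal; entries in
#'   \[-1, 1\] or `NA` for undefined pairs.
#' @export
column_correlation <- function(S, observable = NULL) {
  M <- if (inherits(S, "sensitivity_tensor")) {
    observable_sensitivities(S, observable %||% S$observable)
  } else {
    as.matrix(S)
  }
  sds <- apply(M, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    warning("Zero-variance sensitivity column(s): ",
            paste(colnames(M)[zero], collapse = ", "),
            "; correlations reported as NA.", call. = FALSE)
  }
  cc <- suppressWarnings(stats::cor(M))
  cc[zero, ] <- NA_real_
  cc[, zero] <- NA_real_
  diag(cc) <- ifelse(zero, NA_real_, 1)
  cc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
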