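# Circuit definitions ---------------------------------------------------
#
# Two benchmark synthetic gene circuits driven by doxorubicin (DOX):
#
# * "unbuffered": DOX-induced SKN7m binds the synthetic promoter P_TR-SSRE
#   directly; free SKN7m drives GFP through a Hill term.  3 states
#   (Xm = free SKN7m, Cm = SKN7m-promoter complex, G = GFP),
#   9 kinetic parameters.
# * "buffered": a phosphotransfer driver module (STAT5-HKRR fusion Z,
#   phosphorelay YPD1 = W, SKN7 = X) insulates the reporter from load;
#   doubly phosphorylated SKN7 (Xss) activates GFP.  10 states, 23 kinetic
#   parameters, with retroactivity constants r1, r2.
#
# Units are minutes and uM throughout.  The right-hand sides are kept both
# as hand-coded numeric functions (used by the integrator) and as R
# expression lists (differentiated symbolically for the forward sensitivity
# equations); the two are cross-checked in the test suite.

.unbuffered_states <- c("Xm", "Cm", "G")
.unbuffered_params <- c("k_m", "delta_M", "k_on", "k_off", "delta_C",
                        "p_T", "k_sgfp", "k_g", "delta_G")
.unbuffered_consts <- c("n1", "K_dox", "n2", "K_gfp")

.buffered_states <- c("Z", "Zs", "WT", "Ws", "XT", "Xs", "Xss",
                      "Cs", "Css", "G")
.buffered_params <- c("k_m", "delta_Z", "k1", "k2", "k_p", "k_pp",
                      "k_w", "delta_W", "k_x", "delta_X",
                      "k3", "k4", "k5", "k6", "k7", "r1", "r2",
                      "k_on", "k_off", "delta_C", "k_sgfp", "k_g", "delta_G")
.buffered_consts <- c("n1", "K_dox", "n2", "K_gfp", "p_T")

# RHS as quoted expressions; `u` is the input level, `L` the load factor
# multiplying the total promoter-site concentration p_T.
.unbuffered_exprs <- list(
  Xm = quote(k_m * u^n1 / (K_dox + u^n1) - delta_M * Xm -
               k_on * Xm * (p_T * L - Cm) + k_off * Cm + delta_C * Cm),
  Cm = quote(k_on * Xm * (p_T * L - Cm) - k_off * Cm - delta_C * Cm),
  G  = quote(k_sgfp + k_g * Xm^n2 / (K_gfp + Xm^n2) - delta_G * G)
)

.buffered_exprs <- list(
  Z   = quote(k_m * u^n1 / (K_dox + u^n1) - delta_Z * Z - k2 * Ws * Z +
                k1 * Zs * (WT - Ws) - k_p * Z + k_pp * Zs),
  Zs  = quote(-k1 * Zs * (WT - Ws) + k2 * Ws * Z + k_p * Z - k_pp * Zs -
                delta_Z * Zs),
  WT  = quote(k_w - delta_W * WT),
  Ws  = quote(k1 * Zs * (WT - Ws) - k2 * Ws * Z -
                k3 * (XT - Xs - Xss - Cs - Css) * Ws + k4 * Xs * (WT - Ws) -
                delta_W * Ws - k3 * Xs * Ws + k4 * Xss * (WT - Ws) - k7 * Ws),
  XT  = quote(k_x - delta_X * XT),
  Xs  = quote(k3 * (XT - Xs - Xss - Cs - Css) * Ws - k4 * Xs * (WT - Ws) -
                delta_X * Xs - k3 * Xs * Ws + k4 * Xss * (WT - Ws) -
                k5 * Xs + k6 * Xss + r1),
  Xss = quote(k3 * Xs * Ws - k4 * Xss * (WT - Ws) - k6 * Xss -
                delta_X * Xss + r2),
  Cs  = quote(k_on * Xs * (p_T * L - Cs - Css) - k_off * Cs - delta_C * Cs),
  Css = quote(k_on * Xss * (p_T * L - Cs - Css) - k_off * Css -
                delta_C * Css),
  G   = quote(k_sgfp + k_g * Xss^n2 / (K_gfp + Xss^n2) - delta_G * G)
)

#' Default kinetic parameters for a circuit
#'
#' The original study does not print its parameter values, so these are
#' repository defaults: a documented, biologically plausible regime (rates
#' in 1/min, concentrations in uM) chosen so that the GFP response varies
#' over the feasible DOX range \[1, 30\] uM, the phosphotransfer constraints
#' `k1 >= k3`, `k2 >= k4` and `k1..k4` in \[1, 50\] hold, and the reporter
#' Hill term operates near half-saturation.  Override any entry via
#' [circuit_model()].
#'
#' @param name `"unbuffered"` or `"buffered"`.
#' @return Named numeric vector of kinetic parameters (length 9 or 23).
#' @export
default_params <- function(name = c("unbuffered", "buffered")) {
  name <- match.arg(name)
  if (name == "unbuffered") {
    c(k_m = 0.1, delta_M = 0.05, k_on = 0.2, k_off = 0.02, delta_C = 0.02,
      p_T = 0.5, k_sgfp = 0.001, k_g = 0.05, delta_G = 0.01)
  } else {
    c(k_m = 0.1, delta_Z = 0.05, k1 = 10, k2 = 10, k_p = 0.1, k_pp = 0.05,
      k_w = 0.05, delta_W = 0.05, k_x = 0.05, delta_X = 0.05,
      k3 = 5, k4 = 5, k5 = 0.05, k6 = 0.05, k7 = 0.01,
      r1 = 0.001, r2 = 0.001,
      k_on = 0.2, k_off = 0.02, delta_C = 0.02,
      k_sgfp = 0.001, k_g = 0.05, delta_G = 0.01)
  }
}

#' Default fixed constants for a circuit
#'
#' Hill coefficients `n1`, `n2`, half-saturation constants `K_dox`
#' (uM^n1) and `K_gfp` (uM^n2) and, for the buffered circuit, the total
#' promoter-site concentration `p_T` (uM).  For the unbuffered circuit
#' `p_T` belongs to the kinetic vector instead (see [default_params()]).
#'
#' @inheritParams default_params
#' @return Named numeric vector.
#' @export
default_constants <- function(name = c("unbuffered", "buffered")) {
  name <- match.arg(name)
  if (name == "unbuffered") {
    c(n1 = 2, K_dox = 25, n2 = 2, K_gfp = 4)
  } else {
    c(n1 = 2, K_dox = 25, n2 = 2, K_gfp = 0.01, p_T = 0.5)
  }
}

#' Construct a circuit model
#'
#' Bundles a circuit topology with its kinetic parameters, fixed constants
#' and load condition.  Parameter validity (non-negativity; for the
#' buffered circuit `k1 >= k3`, `k2 >= k4` and `k1..k4` within
#' \[1, 50\] 1/(uM min)) is enforced at construction.
#'
#' @param name `"unbuffered"` or `"buffered"`.
#' @param params Named numeric vector of kinetic-parameter overrides (or a
#'   full vector); defaults from [default_params()].
#' @param constants Named overrides of the fixed constants.
#' @param load_factor 1, 2 or 3 for the unloaded (+0x), single-loaded
#'   (+1x) and double-loaded (+2x) conditions: a multiplier on the total
#'   promoter-site concentration `p_T`.
#' @return A `circuit_model` object.
#' @examples
#' mod <- circuit_model("unbuffered")
#' mod$state_names
#' @export
circuit_model <- function(name = c("unbuffered", "buffered"),
                          params = NULL, constants = NULL, load_factor = 1) {
  name <- match.arg(name)
  p <- default_params(name)
  k <- default_constants(name)
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad)) {
      stop("Unknown kinetic parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(params)] <- params
  }
  if (!is.null(constants)) {
    bad <- setdiff(names(constants), names(k))
    if (length(bad)) {
      stop("Unknown constant(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    k[names(constants)] <- constants
  }
  if (!is.numeric(load_factor) || length(load_factor) != 1L ||
      load_factor <= 0) {
    stop("`load_factor` must be a single positive number.", call. = FALSE)
  }
  validate_circuit_params(name, p, k)
  spec <- circuit_spec(name)
  structure(
    list(name = name,
         state_names = spec$states,
         param_names = spec$params,
         const_names = spec$consts,
         params = p[spec$params],
         constants = k[spec$consts],
         load_factor = load_factor,
         observable = match("G", spec$states)),
    class = "circuit_model"
  )
}

circuit_spec <- function(name) {
  if (name == "unbuffered") {
    list(states = .unbuffered_states, params = .unbuffered_params,
         consts = .unbuffered_consts, exprs = .unbuffered_exprs)
  } else {
    list(states = .buffered_states, params = .buffered_params,
         consts = .buffered_consts, exprs = .buffered_exprs)
  }
}

validate_circuit_params <- function(name, p, k) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("All kinetic parameters must be finite and non-negative.",
         call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("All fixed constants must be finite and positive.", call. = FALSE)
  }
  if (name == "buffered") {
    ks <- p[c("k1", "k2", "k3", "k4")]
    if (any(ks < 1) || any(ks > 50)) {
      stop("Phosphotransfer rates k1..k4 must lie within [1, 50] 1/(uM min).",
           call. = FALSE)
    }
    if (p[["k1"]] < p[["k3"]] || p[["k2"]] < p[["k4"]]) {
      stop("Phosphotransfer constraints require k1 >= k3 and k2 >= k4.",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.circuit_model <- function(x, ...) {
  cat("<circuit_model>", x$name, "circuit:", length(x$state_names),
      "states,", length(x$params), "kinetic parameters",
      sprintf("(load x%g)\n", x$load_factor))
  invisible(x)
}

#' Default initial state of a circuit
#'
#' All species start at zero except, for the buffered circuit, the total
#' phosphorelay and SKN7 pools `WT` and `XT`, which start at their unforced
#' steady states `k_w / delta_W` and `k_x / delta_X` so that no
#' input-independent production transient pollutes the response.
#'
#' @param model A [circuit_model()].
#' @param params Optional kinetic vector overriding `model$params`.
#' @return Named numeric state vector.
#' @export
initial_state <- function(model, params = model$params) {
  y0 <- stats::setNames(numeric(length(model$state_names)),
                        model$state_names)
  if (model$name == "buffered") {
    y0["WT"] <- params[["k_w"]] / params[["delta_W"]]
    y0["XT"] <- params[["k_x"]] / params[["delta_X"]]
  }
  y0
}

# Numeric RHS ------------------------------------------------------------

#' Right-hand side of the unbuffered circuit
#'
#' Time derivatives of (Xm, Cm, G): DOX-activated Hill production of free
#' SKN7m, reversible binding to promoter sites (total `p_T * load`),
#' complex degradation returning SKN7m, and Hill-activated GFP expression
#' with basal rate `k_sgfp`.
#'
#' @param state Numeric 3-vector (Xm, Cm, G) in uM.
#' @param t Time (min).
#' @param params Named kinetic vector, see [default_params()].
#' @param constants Named constant vector, see [default_constants()].
#' @param input An [input_signal][make_input] (or scalar DOX level, uM).
#' @param load_factor Load multiplier on `p_T`.
#' @return Numeric 3-vector of derivatives (uM/min).
#' @export
unbuffered_rhs <- function(state, t, params = default_params("unbuffered"),
                           constants = default_constants("unbuffered"),
                           input = 0, load_factor = 1) {
  check_rhs_args(state, 3L, params, .unbuffered_params)
  u <- rhs_input_level(input, t)
  e <- c(as.list(state_named(state, .unbuffered_states)),
         as.list(params), as.list(constants),
         list(u = u, L = load_factor))
  with(e, {
    hill_in <- k_m * u^n1 / (K_dox + u^n1)
    bind <- k_on * Xm * (p_T * L - Cm)
    c(hill_in - delta_M * Xm - bind + k_off * Cm + delta_C * Cm,
      bind - k_off * Cm - delta_C * Cm,
      k_sgfp + k_g * Xm^n2 / (K_gfp + Xm^n2) - delta_G * G)
  })
}

#' Right-hand side of the buffered circuit
#'
#' Time derivatives of the 10 buffered-circuit states
#' (Z, Zs, WT, Ws, XT, Xs, Xss, Cs, Css, G): DOX-induced STAT5-HKRR (Z),
#' its phosphoform Zs, the YPD1 pool (WT, active Ws), the SKN7 pool
#' (XT; singly/doubly phosphorylated Xs, Xss), promoter complexes
#' Cs, Css, and GFP driven by doubly phosphorylated SKN7.  Retroactivity
#' enters through the constants `r1`, `r2`.
#'
#' @param state Numeric 10-vector in the order above (uM).
#' @inheritParams unbuffered_rhs
#' @return Numeric 10-vector of derivatives (uM/min).
#' @export
buffered_rhs <- function(state, t, params = default_params("buffered"),
                         constants = default_constants("buffered"),
                         input = 0, load_factor = 1) {
  check_rhs_args(state, 10L, params, .buffered_params)
  u <- rhs_input_level(input, t)
  e <- c(as.list(state_named(state, .buffered_states)),
         as.list(params), as.list(constants),
         list(u = u, L = load_factor))
  with(e, {
    hill_in <- k_m * u^n1 / (K_dox + u^n1)
    Xfree <- XT - Xs - Xss - Cs - Css
    Wfree <- WT - Ws
    pfree <- p_T * L - Cs - Css
    c(hill_in - delta_Z * Z - k2 * Ws * Z + k1 * Zs * Wfree -
        k_p * Z + k_pp * Zs,
      -k1 * Zs * Wfree + k2 * Ws * Z + k_p * Z - k_pp * Zs - delta_Z * Zs,
      k_w - delta_W * WT,
      k1 * Zs * Wfree - k2 * Ws * Z - k3 * Xfree * Ws + k4 * Xs * Wfree -
        delta_W * Ws - k3 * Xs * Ws + k4 * Xss * Wfree - k7 * Ws,
      k_x - delta_X * XT,
      k3 * Xfree * Ws - k4 * Xs * Wfree - delta_X * Xs - k3 * Xs * Ws +
        k4 * Xss * Wfree - k5 * Xs + k6 * Xss + r1,
      k3 * Xs * Ws - k4 * Xss * Wfree - k6 * Xss - delta_X * Xss + r2,
      k_on * Xs * pfree - k_off * Cs - delta_C * Cs,
      k_on * Xss * pfree - k_off * Css - delta_C * Css,
      k_sgfp + k_g * Xss^n2 / (K_gfp + Xss^n2) - delta_G * G)
  })
}

circuit_rhs_fn <- function(model) {
  if (model$name == "unbuffered") unbuffered_rhs else buffered_rhs
}

# Closure factory used by the integrator: parameters are unpacked once so
# the per-step derivative call is plain scalar arithmetic.
make_deriv_fn <- function(model, params, input) {
  k <- model$constants
  L <- model$load_factor
  ival <- as.function.input_signal(input)
  if (model$name == "unbuffered") {
    k_m <- params[["k_m"]]; delta_M <- params[["delta_M"]]
    k_on <- params[["k_on"]]; k_off <- params[["k_off"]]
    delta_C <- params[["delta_C"]]; p_T <- params[["p_T"]]
    k_sgfp <- params[["k_sgfp"]]; k_g <- params[["k_g"]]
    delta_G <- params[["delta_G"]]
    n1 <- k[["n1"]]; K_dox <- k[["K_dox"]]
    n2 <- k[["n2"]]; K_gfp <- k[["K_gfp"]]
    pTL <- p_T * L
    function(t, y, parms) {
      u <- ival(t)
      Xm <- y[1]; Cm <- y[2]; G <- y[3]
      un <- u^n1
      bind <- k_on * Xm * (pTL - Cm)
      ret <- (k_off + delta_C) * Cm
      xm2 <- Xm^n2
      list(c(k_m * un / (K_dox + un) - delta_M * Xm - bind + ret,
             bind - ret,
             k_sgfp + k_g * xm2 / (K_gfp + xm2) - delta_G * G))
    }
  } else {
    k_m <- params[["k_m"]]; delta_Z <- params[["delta_Z"]]
    k1 <- params[["k1"]]; k2 <- params[["k2"]]
    k_p <- params[["k_p"]]; k_pp <- params[["k_pp"]]
    k_w <- params[["k_w"]]; delta_W <- params[["delta_W"]]
    k_x <- params[["k_x"]]; delta_X <- params[["delta_X"]]
    k3 <- params[["k3"]]; k4 <- params[["k4"]]; k5 <- params[["k5"]]
    k6 <- params[["k6"]]; k7 <- params[["k7"]]
    r1 <- params[["r1"]]; r2 <- params[["r2"]]
    k_on <- params[["k_on"]]; k_off <- params[["k_off"]]
    delta_C <- params[["delta_C"]]; k_sgfp <- params[["k_sgfp"]]
    k_g <- params[["k_g"]]; delta_G <- params[["delta_G"]]
    n1 <- k[["n1"]]; K_dox <- k[["K_dox"]]
    n2 <- k[["n2"]]; K_gfp <- k[["K_gfp"]]; p_T <- k[["p_T"]]
    pTL <- p_T * L
    function(t, y, parms) {
      u <- ival(t)
      Z <- y[1]; Zs <- y[2]; WT <- y[3]; Ws <- y[4]; XT <- y[5]
      Xs <- y[6]; Xss <- y[7]; Cs <- y[8]; Css <- y[9]; G <- y[10]
      un <- u^n1
      Xfree <- XT - Xs - Xss - Cs - Css
      Wfree <- WT - Ws
      pfree <- pTL - Cs - Css
      t_zw <- k1 * Zs * Wfree - k2 * Ws * Z
      t_xw1 <- k3 * Xfree * Ws - k4 * Xs * Wfree
      t_xw2 <- k3 * Xs * Ws - k4 * Xss * Wfree
      xss2 <- Xss^n2
      list(c(k_m * un / (K_dox + un) - delta_Z * Z + t_zw + k_pp * Zs -
               k_p * Z,
             -t_zw + k_p * Z - k_pp * Zs - delta_Z * Zs,
             k_w - delta_W * WT,
             t_zw - t_xw1 - t_xw2 - delta_W * Ws - k7 * Ws,
             k_x - delta_X * XT,
             t_xw1 - t_xw2 - delta_X * Xs - k5 * Xs + k6 * Xss + r1,
             t_xw2 - k6 * Xss - delta_X * Xss + r2,
             k_on * Xs * pfree - (k_off + delta_C) * Cs,
             k_on * Xss * pfree - (k_off + delta_C) * Css,
             k_sgfp + k_g * xss2 / (K_gfp + xss2) - delta_G * G))
    }
  }
}

check_rhs_args <- function(state, n, params, pnames) {
  if (length(state) != n) {
    stop(sprintf("`state` must have length %d.", n), call. = FALSE)
  }
  if (any(!is.finite(state))) {
    stop("`state` contains non-finite values.", call. = FALSE)
  }
  if (any(!is.finite(params)) || any(params < 0)) {
    stop("Kinetic parameters must be finite and non-negative.",
         call. = FALSE)
  }
  invisible(TRUE)
}

state_named <- function(state, nm) {
  if (is.null(names(state))) names(state) <- nm
  state
}

rhs_input_level <- function(input, t) {
  if (inherits(input, "input_signal")) input_value(input, t)
  else as.numeric(input)
}

# Simulation -------------------------------------------------------------

#' Simulate a circuit trajectory
#'
#' Integrates the circuit ODEs over `time_grid` with a stiff-capable
#' solver (deSolve lsoda).  Integration is restarted at every input
#' discontinuity (step onsets, square-wave edges) so the forcing is
#' resolved exactly.
#'
#' @param model A [circuit_model()].
#' @param input An [input_signal][make_input].
#' @param time_grid Strictly increasing output times starting at 0 (min).
#' @param params Optional kinetic vector overriding `model$params`.
#' @param y0 Optional initial state; default [initial_state()].
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-10).
#' @return A tibble of class `circuit_trajectory` with columns `time`, one
#'   per state, and `input`; the model and input are attached as
#'   attributes.
#' @examples
#' mod <- circuit_model("unbuffered")
#' tr <- simulate_trajectory(mod, make_input("step", 20),
#'                           time_grid = seq(0, 600, by = 10))
#' head(tr)
#' @export
simulate_trajectory <- function(model, input, time_grid,
                                params = model$params, y0 = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "circuit_model"))
  if (!inherits(input, "input_signal")) {
    stop("`input` must be an input_signal from make_input().", call. = FALSE)
  }
  time_grid <- as.numeric(time_grid)
  if (length(time_grid) < 2L || time_grid[1] != 0 ||
      any(diff(time_grid) <= 0)) {
    stop("`time_grid` must be strictly increasing and start at 0.",
         call. = FALSE)
  }
  params <- params[model$param_names]
  validate_circuit_params(model$name, params, model$constants)
  if (is.null(y0)) y0 <- initial_state(model, params)
  deriv <- make_deriv_fn(model, params, input)
  sol <- integrate_piecewise(deriv, y0, time_grid, input, rtol, atol)
  states <- sol[, model$state_names, drop = FALSE]
  if (any(!is.finite(states))) {
    bad_t <- sol[which(!is.finite(rowSums(states)))[1], "time"]
    stop(sprintf("State blow-up: non-finite values at t = %g min.", bad_t),
         call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  out$input <- input_value(input, out$time)
  structure(out, class = c("circuit_trajectory", class(out)),
            model = model, input = input,
            params = params, rtol = rtol, atol = atol)
}

# Integrate `deriv` over `time_grid`, restarting at input discontinuities.
integrate_piecewise <- function(deriv, y0, time_grid, input, rtol, atol,
                                method = "lsoda") {
  t_max <- time_grid[length(time_grid)]
  breaks <- input_breaks(input, t_max)
  edges <- sort(unique(c(time_grid[1], breaks, t_max)))
  rows <- vector("list", length(edges) - 1L)
  y <- y0
  for (i in seq_len(length(edges) - 1L)) {
    a <- edges[i]; b <- edges[i + 1L]
    times <- sort(unique(c(a, time_grid[time_grid > a & time_grid < b], b)))
    seg <- try_ode(y, times, deriv, rtol, atol, method)
    rows[[i]] <- seg[-1, , drop = FALSE]
    y <- seg[nrow(seg), -1]
  }
  out <- rbind(matrix(c(time_grid[1], y0), nrow = 1,
                      dimnames = list(NULL, c("time", names(y0)))),
               do.call(rbind, rows))
  colnames(out)[1] <- "time"
  out[out[, "time"] %in% time_grid, , drop = FALSE]
}

try_ode <- function(y, times, deriv, rtol, atol, method) {
  sol <- deSolve::ode(y = y, times = times, func = deriv, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  diag <- attr(sol, "istate")
  if (!is.null(diag) && diag[1] < 0) {
    stop(sprintf("ODE solver failed near t = %g min (istate = %d).",
                 sol[nrow(sol), 1], diag[1]), call. = FALSE)
  }
  unclass(sol)
}

#' Write a trajectory to CSV
#'
#' Columns `time`, one per state, and `input`; full double precision.
#'
#' @param trajectory A [simulate_trajectory()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
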