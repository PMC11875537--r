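# Numerical integration of community models (deSolve, compiled RHS).

.ode_run <- function(model, y0, times, rtol, atol, method = "lsoda") {
  pv <- .pack_parms(model)
  .install_parms(pv)
  out <- deSolve::ode(y = y0, times = times, func = "plv_derivs",
                      dllname = "plasmidLV", initfunc = "plv_initmod",
                      parms = numeric(0), rtol = rtol, atol = atol,
                      method = method, maxsteps = 20000)
  istate <- attributes(out)$istate
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf(
      "integration failed (istate = %d) for variant '%s', m = %d, eta = %s",
      istate[1], model$variant, model$m,
      paste(signif(range(model$eta), 3), collapse = "..")))
  out
}

.clamp_y <- function(model, y) {
  m <- model$m
  code <- .variant_code(model$variant)
  s <- pmax(y[seq_len(m)], 0)
  if (code == 0L) return(s)
  if (code == 2L) {
    p <- pmin(pmax(y[m + seq_len(m)], 0), s)
    return(c(s, p))
  }
  p <- matrix(y[m + seq_len(m * m)], m, m)
  p <- pmin(pmax(p, 0), matrix(s, m, m))
  diag(p) <- s
  c(s, p)
}

#' Integrate a community model
#'
#' Integrates the variant's ODE system with an adaptive, stiff-capable
#' solver (`deSolve`, lsoda by default). Negative solver output is
#' clamped to 0 and carriers to `[0, s_i]` after integration; the
#' right-hand side itself is left smooth.
#'
#' @param model a `community_model`.
#' @param init a `community_state` (or numeric vector of species
#'   abundances, converted with default carriers).
#' @param t_end end time (hr).
#' @param times optional vector of output times; default 201 equally
#'   spaced points in `[0, t_end]`.
#' @param rtol,atol relative and absolute integration tolerances.
#' @param method deSolve method name.
#' @return object of class `community_trajectory`: list with `times`,
#'   `states` (matrix, one row per time, columns named `s_i` / `p_i_j`),
#'   and `model`.
#' @examples
#' mod <- community_model("classic_lv", m = 2, mu = c(0.5, 0.5),
#'                        gamma = 0.9)
#' tr <- integrate_community(mod, community_state(mod, c(0.1, 0.9)),
#'                           t_end = 500)
#' tail(as.data.frame(tr))
#' @export
integrate_community <- function(model, init, t_end, times = NULL,
                                rtol = 1e-6, atol = 1e-9,
                                method = "lsoda") {
  stopifnot(t_end > 0)
  if (!inherits(init, "community_state"))
    init <- community_state(model, init)
  if (is.null(times)) times <- seq(0, t_end, length.out = 201L)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  out <- .ode_run(model, .state_to_y(model, init), times, rtol, atol, method)
  states <- unname(out[, -1L, drop = FALSE])
  for (k in seq_len(nrow(states))) states[k, ] <- .clamp_y(model, states[k, ])
  colnames(states) <- .state_names(model)
  structure(list(times = out[, 1L], states = states, model = model),
            class = "community_trajectory")
}

#' @export
print.community_trajectory <- function(x, ...) {
  cat("Community trajectory:", length(x$times), "time points over",
      max(x$times), "hr,", ncol(x$states), "state variables\n")
  m <- x$model$m
  cat("  final s:", paste(signif(x$states[nrow(x$states), seq_len(m)], 4),
                          collapse = " "), "\n")
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x a `community_trajectory`.
#' @param ... unused.
#' @return data.frame with columns `time`, `entity` (`"s_i"`/`"p_i_j"`),
#'   `value`, ready for CSV export.
#' @export
as.data.frame.community_trajectory <- function(x, ...) {
  data.frame(
    time = rep(x$times, times = ncol(x$states)),
    entity = rep(colnames(x$states), each = length(x$times)),
    value = as.vector(x$states))
}

#' Final state of a trajectory
#'
#' @param trajectory a `community_trajectory`.
#' @return a `community_state`.
#' @export
final_state <- function(trajectory) {
  .y_to_state(trajectory$model,
              trajectory$states[nrow(trajectory$states), ])
}

#' Integrate to steady state
#'
#' Integrates for `horizon` hours, then checks the equilibrium residual
#' `max |dy/dt|` at the final state. If it still exceeds `tol` the run is
#' extended in `step`-hour increments up to `max_horizon`, and the result
#' flagged accordingly: a fixed simulation horizon alone can misclassify
#' slow transients as equilibria.
#'
#' @param model a `community_model`.
#' @param init initial `community_state` (or abundance vector).
#' @param horizon first integration horizon (hr).
#' @param tol convergence tolerance on `max |dy/dt|` (1/hr).
#' @param step extension increment (hr).
#' @param max_horizon hard cap on total simulated time (hr).
#' @param rtol,atol integration tolerances.
#' @param method deSolve method name.
#' @return object of class `steady_state`: list with `state`
#'   (a clamped `community_state`), `converged`, `residual`, `t_final`.
#' @export
find_steady_state <- function(model, init, horizon = 2000, tol = 1e-6,
                              step = 500, max_horizon = 10000,
                              rtol = 1e-6, atol = 1e-9, method = "lsoda") {
  if (!inherits(init, "community_state"))
    init <- community_state(model, init)
  pv <- .pack_parms(model)
  y <- .state_to_y(model, init)
  t_total <- 0
  chunk <- horizon
  repeat {
    out <- .ode_run(model, y, c(0, chunk), rtol, atol, method)
    y <- .clamp_y(model, out[nrow(out), -1L])
    t_total <- t_total + chunk
    residual <- max(abs(.Call(C_eval_derivs, pv, as.double(y))))
    if (residual < tol || t_total >= max_horizon) break
    chunk <- step
  }
  structure(list(state = .y_to_state(model, y),
                 converged = residual < tol,
                 residual = residual, t_final = t_total, model = model),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("Steady state after", x$t_final, "hr (",
      if (x$converged) "converged" else "NOT converged",
      ", residual", signif(x$residual, 3), ")\n")
  cat("  s:", paste(signif(x$state$s, 4), collapse = " "), "\n")
  invisible(x)
}

#' Detect a sustained oscillation in a trajectory
#'
#' Proxy check for a limit cycle: the state at the final time and at
#' `window` hours earlier differ by more than `threshold` (Euclidean
#' distance on species abundances) while the dynamics at both times are
#' still moving (residual above `tol`). Damped transients and fixed
#' points both return `FALSE`.
#'
#' @param trajectory a `community_trajectory` covering at least
#'   `2 * window` hours.
#' @param window comparison lag (hr).
#' @param threshold distance threshold (defaults to the attractor
#'   clustering scale, 0.05).
#' @param tol residual tolerance (1/hr).
#' @param deriv optional derivative function `function(y) dy` overriding
#'   the model right-hand side (for synthetic test fields).
#' @return logical scalar.
#' @export
detect_limit_cycle <- function(trajectory, window, threshold = 0.05,
                               tol = 1e-6, deriv = NULL) {
  tt <- trajectory$times
  if (max(tt) - min(tt) < 2 * window)
    stop("trajectory must cover at least twice the comparison window")
  model <- trajectory$model
  m <- model$m
  i_end <- length(tt)
  i_lag <- which.min(abs(tt - (tt[i_end] - window)))
  y_end <- trajectory$states[i_end, ]
  y_lag <- trajectory$states[i_lag, ]
  if (is.null(deriv)) {
    pv <- .pack_parms(model)
    deriv <- function(y) .Call(C_eval_derivs, pv, as.double(y))
  }
  r_end <- max(abs(deriv(y_end)))
  r_lag <- max(abs(deriv(y_lag)))
  d <- sqrt(sum((y_end[seq_len(m)] - y_lag[seq_len(m)])^2))
  d > threshold && r_end > tol && r_lag > tol
}
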