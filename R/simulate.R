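# central finite differences for model Jacobians when the plugin does not
# provide analytic ones; step scaled to the argument magnitude
fd_jacobian <- function(fn, at, n_out, h_rel = 1e-6) {
  n <- length(at)
  J <- matrix(0, n_out, n)
  for (j in seq_len(n)) {
    h <- h_rel * max(abs(at[j]), 1)
    ap <- at; ap[j] <- at[j] + h
    am <- at; am[j] <- at[j] - h
    J[, j] <- (fn(ap) - fn(am)) / (2 * h)
  }
  J
}

model_jacobians <- function(model) {
  jx <- model$jac_state %||%
    function(t, x, theta) fd_jacobian(function(z) model$rhs(t, z, theta), x,
                                      model$n_states)
  jp <- model$jac_param %||%
    function(t, x, theta) fd_jacobian(function(z) model$rhs(t, x, z), theta,
                                      model$n_states)
  j0 <- model$init_jac %||%
    function(theta) fd_jacobian(model$initial_state, theta, model$n_states)
  list(jac_state = jx, jac_param = jp, init_jac = j0)
}

observation_jacobians <- function(obs) {
  hx <- obs$jac_state %||%
    function(x, theta) fd_jacobian(function(z) obs$observe(z, theta), x,
                                   obs$n_observables)
  hp <- obs$jac_param %||%
    function(x, theta) fd_jacobian(function(z) obs$observe(x, z), theta,
                                   obs$n_observables)
  list(jac_state = hx, jac_param = hp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an ODE model and its forward sensitivities
#'
#' Integrates \eqn{\dot x = f(x, \theta)} with a stiff-capable solver
#' (`deSolve::lsoda`) and, if requested, the variational system
#' \eqn{\dot S_x = (\partial f/\partial x) S_x + \partial f/\partial \theta}
#' with \eqn{S_x(t_0) = \partial x_0/\partial \theta} as one augmented
#' system. Observables are obtained by applying the observation map at every
#' requested time; observable sensitivities follow by the chain rule
#' \eqn{S_y = (\partial h/\partial x) S_x + \partial h/\partial \theta}.
#'
#' Integrator failures are encoded in the result (`status =
#' "solver_failure"`), never raised, so that multi-start optimization is
#' robust to pathological parameter draws.
#'
#' @param ode_model an [ode_model()].
#' @param observation_model an [observation_model()], or `NULL` to skip
#'   observable evaluation.
#' @param theta dynamic parameter vector (natural scale).
#' @param times sorted ascending vector of output times, all `>= t0`.
#' @param with_sensitivities logical; integrate the variational system?
#' @param atol,rtol absolute / relative integration tolerances.
#' @return a list of class `simulation_result` with elements `times`,
#'   `states` (time x n_states), `state_sensitivities`
#'   (time x n_states x n_dynamic or `NULL`), `observables`
#'   (time x n_observables or `NULL`), `observable_sensitivities`, `status`.
#' @export
simulate_model <- function(ode_model, observation_model, theta, times,
                           with_sensitivities = FALSE,
                           atol = 1e-8, rtol = 1e-6) {
  stopifnot(inherits(ode_model, "ode_model"))
  if (is.unsorted(times)) stop("times must be sorted ascending", call. = FALSE)
  if (any(times < ode_model$t0)) stop("times must be >= t0", call. = FALSE)
  nx <- ode_model$n_states
  np <- ode_model$n_dynamic
  if (length(theta) != np)
    stop("theta must have length n_dynamic = ", np, call. = FALSE)

  full_times <- unique(c(ode_model$t0, times))
  jac <- model_jacobians(ode_model)

  x0 <- ode_model$initial_state(theta)
  if (with_sensitivities) {
    y0 <- c(x0, as.vector(jac$init_jac(theta)))
    deriv <- function(t, y, parms) {
      x <- y[seq_len(nx)]
      dx <- ode_model$rhs(t, x, theta)
      Sx <- matrix(y[-seq_len(nx)], nx, np)
      dS <- jac$jac_state(t, x, theta) %*% Sx + jac$jac_param(t, x, theta)
      list(c(dx, as.vector(dS)))
    }
  } else {
    y0 <- x0
    deriv <- function(t, y, parms) list(ode_model$rhs(t, y, theta))
  }

  fail <- function() {
    structure(list(times = times, states = NULL, state_sensitivities = NULL,
                   observables = NULL, observable_sensitivities = NULL,
                   status = "solver_failure"),
              class = "simulation_result")
  }
  out <- tryCatch(
    suppressWarnings(deSolve::lsoda(y0, full_times, deriv, parms = NULL,
                                    atol = atol, rtol = rtol, maxsteps = 10000)),
    error = function(e) NULL)
  if (is.null(out) || nrow(out) != length(full_times) || anyNA(out))
    return(fail())

  keep <- match(times, full_times)
  states <- out[keep, 1 + seq_len(nx), drop = FALSE]
  colnames(states) <- ode_model$state_names
  state_sens <- NULL
  if (with_sensitivities) {
    state_sens <- array(out[keep, 1 + nx + seq_len(nx * np)],
                        dim = c(length(times), nx, np),
                        dimnames = list(NULL, ode_model$state_names,
                                        ode_model$parameter_names))
  }

  observables <- obs_sens <- NULL
  if (!is.null(observation_model)) {
    ny <- observation_model$n_observables
    observables <- matrix(0, length(times), ny,
                          dimnames = list(NULL, observation_model$observable_names))
    ojac <- if (with_sensitivities) observation_jacobians(observation_model)
    if (with_sensitivities)
      obs_sens <- array(0, dim = c(length(times), ny, np),
                        dimnames = list(NULL, observation_model$observable_names,
                                        ode_model$parameter_names))
    for (r in seq_along(times)) {
      x <- states[r, ]
      observables[r, ] <- observation_model$observe(x, theta)
      if (with_sensitivities) {
        obs_sens[r, , ] <- ojac$jac_state(x, theta) %*% state_sens[r, , ] +
          ojac$jac_param(x, theta)
      }
    }
  }

  structure(list(times = times, states = states,
                 state_sensitivities = state_sens,
                 observables = observables,
                 observable_sensitivities = obs_sens,
                 status = "ok"),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> status=", x$status, ", ", length(x$times),
      " time points", if (!is.null(x$state_sensitivities)) ", with sensitivities",
      "\n", sep = "")
  invisible(x)
}
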