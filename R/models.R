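#' Define an ODE model plugin
#'
#' An ODE model is the dynamic core of an estimation problem:
#' \deqn{\dot x = f(x(t,\theta), \theta), \qquad x(t_0,\theta) = x_0(\theta),}
#' with state vector \eqn{x} (species concentrations) and dynamic parameters
#' \eqn{\theta} (rate constants and parameter-dependent initial conditions).
#'
#' Jacobians of the right-hand side may be supplied for speed; when absent
#' they are obtained by central finite differences, which is accurate enough
#' for the forward sensitivity system at the default solver tolerances.
#'
#' @param name identifier for the model.
#' @param rhs function `(t, x, theta) -> dx/dt`, returning a numeric vector of
#'   length `n_states`.
#' @param initial_state function `(theta) -> x(t0)`, length `n_states`.
#' @param n_states,n_dynamic number of state variables and of dynamic
#'   parameters.
#' @param t0 initial time (default 0).
#' @param state_names,parameter_names identifiers; defaults `x1, x2, ...` and
#'   `theta1, ...`.
#' @param jac_state optional function `(t, x, theta)` returning the
#'   `n_states x n_states` Jacobian \eqn{\partial f/\partial x}.
#' @param jac_param optional function `(t, x, theta)` returning the
#'   `n_states x n_dynamic` Jacobian \eqn{\partial f/\partial \theta}.
#' @param init_jac optional function `(theta)` returning the
#'   `n_states x n_dynamic` Jacobian \eqn{\partial x_0/\partial \theta}.
#' @return an object of class `ode_model`.
#' @export
ode_model <- function(name, rhs, initial_state, n_states, n_dynamic, t0 = 0,
                      state_names = paste0("x", seq_len(n_states)),
                      parameter_names = paste0("theta", seq_len(n_dynamic)),
                      jac_state = NULL, jac_param = NULL, init_jac = NULL) {
  stopifnot(is.function(rhs), is.function(initial_state),
            n_states >= 1, n_dynamic >= 1,
            length(state_names) == n_states,
            length(parameter_names) == n_dynamic)
  theta_probe <- rep(0.5, n_dynamic)
  x0 <- initial_state(theta_probe)
  if (length(x0) != n_states)
    stop("initial_state() must return a vector of length n_states", call. = FALSE)
  if (length(rhs(t0, x0, theta_probe)) != n_states)
    stop("rhs() must return a vector of length n_states", call. = FALSE)
  structure(
    list(name = name, rhs = rhs, initial_state = initial_state,
         n_states = as.integer(n_states), n_dynamic = as.integer(n_dynamic),
         t0 = t0, state_names = state_names, parameter_names = parameter_names,
         jac_state = jac_state, jac_param = jac_param, init_jac = init_jac),
    class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model> ", x$name, ": ", x$n_states, " states, ",
      x$n_dynamic, " dynamic parameters\n", sep = "")
  invisible(x)
}

#' Define an observation model
#'
#' Maps states (and dynamic parameters) to the observables that are actually
#' measured, \eqn{y(t,\theta) = h(x(t,\theta),\theta)}. Relative measurements
#' are modelled downstream as \eqn{\bar y_{i,k} = s_i \, h_i + \varepsilon_{i,k}};
#' the scaling factor is *not* part of `observe`.
#'
#' @param observe function `(x, theta) -> y`, length `n_observables`.
#' @param n_observables number of observables.
#' @param observable_names identifiers, default `obs1, ...`.
#' @param observation_scale per-observable scale on which residuals are
#'   formed: `"linear"` or `"log10"` (recycled if length 1).
#' @param jac_state optional `(x, theta)` returning
#'   \eqn{\partial h/\partial x} (`n_observables x n_states`).
#' @param jac_param optional `(x, theta)` returning
#'   \eqn{\partial h/\partial \theta} (`n_observables x n_dynamic`).
#' @return an object of class `observation_model`.
#' @export
observation_model <- function(observe, n_observables,
                              observable_names = paste0("obs", seq_len(n_observables)),
                              observation_scale = "linear",
                              jac_state = NULL, jac_param = NULL) {
  stopifnot(is.function(observe), n_observables >= 1,
            length(observable_names) == n_observables)
  observation_scale <- rep_len(observation_scale, n_observables)
  if (!all(observation_scale %in% c("linear", "log10")))
    stop("observation_scale must be 'linear' or 'log10'", call. = FALSE)
  structure(
    list(observe = observe, n_observables = as.integer(n_observables),
         observable_names = observable_names,
         observation_scale = stats::setNames(observation_scale, observable_names),
         jac_state = jac_state, jac_param = jac_param),
    class = "observation_model")
}

#' @export
print.observation_model <- function(x, ...) {
  cat("<observation_model> ", x$n_observables, " observables: ",
      paste(x$observable_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- built-in models ------------------------------------------------------

#' Built-in ODE model plugins
#'
#' Three small signaling-motif models used by the synthetic benchmark
#' generator, each with analytic Jacobians:
#' \describe{
#'   \item{`conversion_reaction`}{reversible conversion \eqn{A \rightleftharpoons B}
#'     with rates `k1`, `k2`; states `A`, `B`, initial condition (1, 0).
#'     Both species are observed.}
#'   \item{`cascade3`}{three-tier phosphorylation cascade (the structure of a
#'     RAF/MEK/ERK-type pathway): each tier has an active fraction
#'     \eqn{x_j \in [0,1]} driven by the tier above,
#'     \eqn{\dot x_1 = k_1(1-x_1) - k_2 x_1},
#'     \eqn{\dot x_2 = k_3 x_1 (1-x_2) - k_4 x_2},
#'     \eqn{\dot x_3 = k_5 x_2 (1-x_3) - k_6 x_3}. The cascade is observed in
#'     a washout design: at \eqn{t_0} the cells are in a stimulated state
#'     \eqn{x(0) = (0.9, 0.8, 0.6)} and relax after stimulus reduction. The
#'     known nonzero initial phosphorylation anchors the absolute scale of
#'     the trajectories, which keeps the scaling parameters identifiable
#'     from relative data. The two lower tiers (pMEK- and pERK-like) are
#'     observed.}
#'   \item{`spline_input_pathway`}{receptor-driven pathway (JAK-STAT-type
#'     structure): a fixed smooth input \eqn{u(t) = e^{-0.2t} - e^{-2t}}
#'     (sum of two exponentials standing in for the measured receptor
#'     time course) drives phosphorylation,
#'     \eqn{\dot x_1 = k_1 u(t) (1 - x_1 - x_2) - k_2 x_1},
#'     \eqn{\dot x_2 = k_2 x_1 - k_3 x_2}; observables are the
#'     phosphorylated pool \eqn{x_1} and the total cytoplasmic pool
#'     \eqn{1 - x_2}.}
#' }
#'
#' @param name one of `"conversion_reaction"`, `"cascade3"`,
#'   `"spline_input_pathway"`.
#' @return a list with elements `model` (an [ode_model()]) and `observation`
#'   (an [observation_model()]).
#' @export
builtin_model <- function(name = c("conversion_reaction", "cascade3",
                                   "spline_input_pathway")) {
  name <- match.arg(name)
  switch(name,
    conversion_reaction = builtin_conversion_reaction(),
    cascade3 = builtin_cascade3(),
    spline_input_pathway = builtin_spline_input_pathway())
}

builtin_conversion_reaction <- function() {
  model <- ode_model(
    name = "conversion_reaction",
    rhs = function(t, x, theta) {
      flux <- theta[1] * x[1] - theta[2] * x[2]
      c(-flux, flux)
    },
    initial_state = function(theta) c(1, 0),
    n_states = 2, n_dynamic = 2,
    state_names = c("A", "B"), parameter_names = c("k1", "k2"),
    jac_state = function(t, x, theta)
      matrix(c(-theta[1], theta[1], theta[2], -theta[2]), 2, 2),
    jac_param = function(t, x, theta)
      matrix(c(-x[1], x[1], x[2], -x[2]), 2, 2),
    init_jac = function(theta) matrix(0, 2, 2))
  observation <- observation_model(
    observe = function(x, theta) x,
    n_observables = 2, observable_names = c("A", "B"),
    jac_state = function(x, theta) diag(2),
    jac_param = function(x, theta) matrix(0, 2, 2))
  list(model = model, observation = observation)
}

builtin_cascade3 <- function() {
  model <- ode_model(
    name = "cascade3",
    rhs = function(t, x, theta) {
      c(theta[1] * (1 - x[1]) - theta[2] * x[1],
        theta[3] * x[1] * (1 - x[2]) - theta[4] * x[2],
        theta[5] * x[2] * (1 - x[3]) - theta[6] * x[3])
    },
    initial_state = function(theta) c(0.9, 0.8, 0.6),
    n_states = 3, n_dynamic = 6,
    state_names = c("pRAF", "pMEK", "pERK"),
    parameter_names = c("k1", "k2", "k3", "k4", "k5", "k6"),
    jac_state = function(t, x, theta) {
      matrix(c(-theta[1] - theta[2], theta[3] * (1 - x[2]), 0,
               0, -theta[3] * x[1] - theta[4], theta[5] * (1 - x[3]),
               0, 0, -theta[5] * x[2] - theta[6]),
             3, 3)
    },
    jac_param = function(t, x, theta) {
      matrix(c(1 - x[1], 0, 0,
               -x[1], 0, 0,
               0, x[1] * (1 - x[2]), 0,
               0, -x[2], 0,
               0, 0, x[2] * (1 - x[3]),
               0, 0, -x[3]),
             3, 6)
    },
    init_jac = function(theta) matrix(0, 3, 6))
  observation <- observation_model(
    observe = function(x, theta) x[2:3],
    n_observables = 2, observable_names = c("pMEK", "pERK"),
    jac_state = function(x, theta)
      matrix(c(0, 0, 1, 0, 0, 1), 2, 3),
    jac_param = function(x, theta) matrix(0, 2, 6))
  list(model = model, observation = observation)
}

# fixed receptor-like input for the spline-input pathway
spline_input_u <- function(t) exp(-0.2 * t) - exp(-2 * t)

builtin_spline_input_pathway <- function() {
  model <- ode_model(
    name = "spline_input_pathway",
    rhs = function(t, x, theta) {
      u <- spline_input_u(t)
      c(theta[1] * u * (1 - x[1] - x[2]) - theta[2] * x[1],
        theta[2] * x[1] - theta[3] * x[2])
    },
    initial_state = function(theta) c(0, 0),
    n_states = 2, n_dynamic = 3,
    state_names = c("pSTAT", "nSTAT"),
    parameter_names = c("k_act", "k_imp", "k_exp"),
    jac_state = function(t, x, theta) {
      u <- spline_input_u(t)
      matrix(c(-theta[1] * u - theta[2], theta[2],
               -theta[1] * u, -theta[3]),
             2, 2)
    },
    jac_param = function(t, x, theta) {
      u <- spline_input_u(t)
      matrix(c(u * (1 - x[1] - x[2]), 0,
               -x[1], x[1],
               0, -x[2]),
             2, 3)
    },
    init_jac = function(theta) matrix(0, 2, 3))
  observation <- observation_model(
    observe = function(x, theta) c(x[1], 1 - x[2]),
    n_observables = 2, observable_names = c("pSTAT", "tSTAT"),
    jac_state = function(x, theta) matrix(c(1, 0, 0, -1), 2, 2),
    jac_param = function(x, theta) matrix(0, 2, 3))
  list(model = model, observation = observation)
}
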