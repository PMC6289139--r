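# Diagnostic figures: likelihood waterfalls and fitted-trajectory overlays.

#' Likelihood waterfall plot
#'
#' Final negative log-likelihood values of all starts, sorted ascending.
#' Starts within the convergence threshold of the best value are the
#' "converged" plateau at the left edge; a long flat plateau indicates
#' reliable convergence of the multi-start optimization.
#'
#' @param x a `multistart_result` or `comparison_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_waterfall <- function(x, ...) {
  df <- if (inherits(x, "comparison_report")) {
    purrr::imap_dfr(x$waterfalls, function(J, name)
      tibble::tibble(approach = name, index = seq_along(J), J = J))
  } else if (inherits(x, "multistart_result")) {
    tibble::tibble(approach = x$approach, index = seq_len(nrow(x$starts)),
                   J = sort(x$starts$J))
  } else stop("plot_waterfall() expects a multistart_result or comparison_report",
              call. = FALSE)
  df <- df[is.finite(df$J), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$J,
                                   colour = .data$approach)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "sorted start index", y = "negative log-likelihood",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.multistart_result <- function(object, ...) plot_waterfall(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.comparison_report <- function(object, ...) plot_waterfall(object, ...)

#' Overlay fitted trajectories on the scaled measurements
#'
#' Simulates the model at `theta` on a fine grid and plots the scaled
#' trajectories \eqn{s \cdot h_i(t)} per observable, overlaid with the
#' measurements; each record is drawn with its group's scaling so relative
#' data from different blots/replicates are comparable.
#'
#' @param problem an `estimation_problem`.
#' @param theta dynamic parameters.
#' @param scalings named vector over the free scaling groups (fixed groups
#'   are filled in automatically); e.g. `fit$best_parameters$scalings`.
#' @param n_grid number of time points for the smooth trajectory.
#' @return a ggplot object.
#' @export
plot_fit <- function(problem, theta, scalings, n_grid = 200) {
  stopifnot(inherits(problem, "estimation_problem"))
  s_full <- full_scaling_vector(problem, scalings)
  tgrid <- seq(problem$ode_model$t0, max(problem$times), length.out = n_grid)
  sim <- simulate_model(problem$ode_model, problem$observation_model, theta,
                        tgrid)
  if (sim$status != "ok") stop("simulation failed at theta", call. = FALSE)
  m <- problem$measurements
  # one trajectory per scaling group (groups may differ within an observable)
  groups <- dplyr::distinct(m, .data$observableId, .data$scalingId)
  traj <- purrr::pmap_dfr(groups, function(observableId, scalingId) {
    scaled <- unname(s_full[scalingId]) * sim$observables[, observableId]
    tibble::tibble(observableId = observableId, scalingId = scalingId,
                   time = tgrid, value = scaled)
  })
  ggplot2::ggplot() +
    ggplot2::geom_line(data = traj,
                       ggplot2::aes(x = .data$time, y = .data$value,
                                    group = .data$scalingId)) +
    ggplot2::geom_point(data = m,
                        ggplot2::aes(x = .data$time, y = .data$measurement,
                                     shape = .data$replicateId),
                        colour = "firebrick", alpha = 0.8) +
    ggplot2::facet_wrap(~observableId, scales = "free_y") +
    ggplot2::labs(x = "time", y = "scaled observable", shape = "replicate") +
    ggplot2::theme_minimal()
}
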