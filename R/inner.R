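# Inner subproblem: conditionally optimal scaling and noise parameters
# (s-hat, sigma-hat) given the simulated observables at fixed dynamic
# parameters. Nothing in this file touches the ODE integrator -- the whole
# point of the hierarchical formulation is that the inner problem is solved
# on already-simulated observables.

#' Closed-form inner optimum for Gaussian noise (one group)
#'
#' For a group of records sharing one scaling and one noise parameter, the
#' Gaussian negative log-likelihood is minimized uniquely by
#' \deqn{\hat s = \frac{\sum_k \bar y_k h_k}{\sum_k h_k^2}, \qquad
#'       \hat\sigma^2 = \frac{1}{n}\sum_k (\bar y_k - \hat s h_k)^2.}
#' Note the \eqn{1/n} (maximum-likelihood, biased) variance estimator.
#'
#' @param h_values simulated observable values of the group's records.
#' @param y_values measured values, same length.
#' @return list with elements `s` and `sigma2`.
#' @export
gaussian_inner <- function(h_values, y_values) {
  stopifnot(length(h_values) == length(y_values), length(h_values) >= 1)
  den <- sum(h_values^2)
  if (den == 0)
    stop("degenerate group: all simulated observables are zero, ",
         "scaling unidentifiable", call. = FALSE)
  s_hat <- sum(y_values * h_values) / den
  r <- y_values - s_hat * h_values
  list(s = s_hat, sigma2 = mean(r^2))
}

#' Kink-search for the optimal Laplace scaling parameter (one group)
#'
#' The Laplace objective is piecewise linear in the scaling parameter with
#' kinks at the jump points \eqn{s_k = \bar y_k / h_k} (records with
#' \eqn{h_k = 0} contribute no jump point: their term does not depend on
#' \eqn{s}). The derivative between kinks is
#' \eqn{\partial J/\partial s = -(1/\sigma)\sum_k |h_k|\,
#' \mathrm{sgn}(\bar y_k/h_k - s)}; the jump points are sorted and the
#' derivative sign is evaluated at the midpoints of adjacent kinks, and the
#' optimum is the kink where the sign flips from negative to positive. When
#' the derivative is exactly zero on a segment (even total weight) the lower
#' adjacent jump point is returned; any point of the flat segment attains
#' the same objective. No ODE simulation is involved.
#'
#' @inheritParams gaussian_inner
#' @return the optimal scaling \eqn{\hat s} (a jump point), with the sorted
#'   jump points attached as attribute `"jump_points"`.
#' @export
laplace_inner_scaling <- function(h_values, y_values) {
  stopifnot(length(h_values) == length(y_values), length(h_values) >= 1)
  nz <- h_values != 0
  if (!any(nz))
    stop("degenerate group: all simulated observables are zero, ",
         "scaling unidentifiable", call. = FALSE)
  h <- h_values[nz]
  y <- y_values[nz]
  jumps <- y / h
  ord <- order(jumps)
  jumps <- jumps[ord]
  w <- abs(h)[ord]
  u <- unique(jumps)
  if (length(u) == 1) {
    s_hat <- u
  } else {
    # derivative sign on each open segment between adjacent distinct kinks,
    # evaluated at the segment midpoint
    mids <- (u[-length(u)] + u[-1]) / 2
    dJ <- vapply(mids, function(s) -sum(w * sign(jumps - s)), numeric(1))
    pos <- which(dJ >= 0)
    # below u[1] the derivative is -sum(w) < 0, above u[m] it is +sum(w) > 0:
    # a sign change always exists; zero on a segment means a flat optimum and
    # the lower adjacent kink is returned
    s_hat <- if (length(pos) == 0) u[length(u)] else u[pos[1]]
  }
  structure(s_hat, jump_points = u)
}

#' Optimal Laplace noise parameter given the scaling (one group)
#'
#' \deqn{\hat\sigma = \frac{1}{n}\sum_k |h_k|\,|\bar y_k/h_k - \hat s|
#'   = \frac{1}{n}\sum_k |\bar y_k - \hat s h_k|,}
#' the mean absolute residual (the second form also covers records with
#' \eqn{h_k = 0}, whose contribution is independent of \eqn{s}).
#'
#' @inheritParams gaussian_inner
#' @param s_hat the (finite) scaling at which residuals are taken.
#' @return the optimal scale \eqn{\hat\sigma \ge 0}.
#' @export
laplace_inner_noise <- function(h_values, y_values, s_hat) {
  stopifnot(is.finite(s_hat))
  mean(abs(y_values - s_hat * h_values))
}

#' Closed-form inner optimum for Gaussian noise on the log10 scale (one group)
#'
#' With residuals formed on the log10 scale the scaling acts as an additive
#' shift, so
#' \deqn{\log_{10}\hat s = \frac{1}{n}\sum_k (\log_{10}\bar y_k -
#'   \log_{10} h_k), \qquad
#'   \hat\sigma^2 = \frac{1}{n}\sum_k (\log_{10}\bar y_k - \log_{10} h_k -
#'   \log_{10}\hat s)^2.}
#'
#' @inheritParams gaussian_inner
#' @return list with elements `s` and `sigma2`.
#' @export
log10_gaussian_inner <- function(h_values, y_values) {
  stopifnot(length(h_values) == length(y_values), length(h_values) >= 1)
  if (any(h_values <= 0) || any(y_values <= 0))
    stop("log10-scale inner solver requires strictly positive simulated ",
         "and measured values", call. = FALSE)
  d <- log10(y_values) - log10(h_values)
  ls <- mean(d)
  list(s = 10^ls, sigma2 = mean((d - ls)^2))
}

# weighted lower median of `x` with nonnegative weights `w`: smallest x with
# cumulative weight >= half the total (matches the kink-search tie-break)
weighted_lower_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  x[which(cw >= cw[length(cw)] / 2)[1]]
}

# split a problem's records by free scaling / noise group
group_records <- function(problem) {
  m <- problem$measurements
  list(by_scaling = split(seq_len(nrow(m)), m$scalingId),
       by_noise = split(seq_len(nrow(m)), m$noiseId))
}

#' Solve the inner subproblem: optimal scaling and noise parameters
#'
#' Given the simulated observables at fixed dynamic parameters, computes the
#' conditionally optimal scaling and noise parameters per group. When every
#' free scaling group's records share a single noise parameter (the usual
#' layout, including the per-observable default), the solution is fully
#' analytic: closed-form Gaussian expressions, the Laplace kink-search, or
#' the log10-scale closed form, applied group by group. When a free scaling
#' group spans several free noise groups (coupled sharing, e.g. one scaling
#' shared across observables with distinct unknown noises) the solver falls
#' back to coordinate descent alternating closed-form blocks:
#' precision-weighted scaling updates
#' (\eqn{\hat s = \sum \bar y h/\sigma^2 / \sum h^2/\sigma^2} for Gaussian,
#' \eqn{|h|/\sigma}-weighted medians for Laplace) and closed-form noise
#' updates, until the objective decrease is below `1e-10` or 100 iterations.
#' The descent is monotone for Gaussian; for Laplace monotonicity is
#' asserted per iteration and a violating scaling update is replaced by a
#' one-dimensional refinement over the group's jump-point range.
#'
#' No step of this function invokes the ODE integrator: the inner problem is
#' solved entirely on the already-simulated observables.
#'
#' @param problem an [build_problem()] result.
#' @param simulated either a `simulation_result` for the problem's time grid
#'   or a numeric vector of simulated observable values, one per measurement
#'   record.
#' @param theta optional dynamic parameters used only as provenance in the
#'   returned object.
#' @return an object of class `inner_solution`: named vectors `scalings` and
#'   `noises` over all groups (fixed groups carry their fixed values),
#'   `method_used`, `jump_points` (Laplace diagnostics, per group),
#'   `iterations`, `status`.
#' @export
solve_inner <- function(problem, simulated, theta = NULL) {
  stopifnot(inherits(problem, "estimation_problem"))
  h <- if (inherits(simulated, "simulation_result")) {
    if (simulated$status != "ok")
      stop("cannot solve the inner problem on a failed simulation", call. = FALSE)
    record_observables(problem, simulated)$h
  } else as.numeric(simulated)
  m <- problem$measurements
  if (length(h) != nrow(m))
    stop("need one simulated observable value per measurement record",
         call. = FALSE)
  if (any(h < -1e-8) && problem$noise_distribution == "laplace")
    warning("negative simulated observables encountered; ratios remain ",
            "well-defined but concentrations are expected non-negative")

  dist <- problem$noise_distribution
  y <- m$measurement
  grp <- group_records(problem)
  scalings <- c(stats::setNames(rep(NA_real_, length(problem$free_scaling_ids)),
                                problem$free_scaling_ids),
                problem$fixed_scalings)
  noises <- c(stats::setNames(rep(NA_real_, length(problem$free_noise_ids)),
                              problem$free_noise_ids),
              problem$fixed_noises)
  jump_points <- list()

  # a free scaling group is analytically solvable in one pass iff its
  # records carry a single noise parameter (free or fixed) or only fixed
  # noise values; otherwise the unknown sigmas weight the s-update
  coupled <- FALSE
  for (g in problem$free_scaling_ids) {
    nids <- unique(m$noiseId[grp$by_scaling[[g]]])
    n_free <- sum(nids %in% problem$free_noise_ids)
    if (length(nids) > 1 && n_free > 0) coupled <- TRUE
    scales_g <- unique(m$obs_scale[grp$by_scaling[[g]]])
    if (length(scales_g) > 1)
      stop("scaling group '", g, "' mixes linear and log10 observables; ",
           "unsupported", call. = FALSE)
  }

  iterations <- 0L

  if (!coupled) {
    # one exact sweep: each s-hat is independent of the (possibly unknown)
    # noise values because sigma is constant within the group or known
    for (g in problem$free_scaling_ids) {
      idx <- grp$by_scaling[[g]]
      sc <- m$obs_scale[idx[1]]
      nids <- unique(m$noiseId[idx])
      if (length(nids) > 1) {
        # several *fixed* noises: precision-weighted closed form
        w <- 1 / pmax(noises[m$noiseId[idx]], SIGMA_FLOOR)^2
        if (sc == "log10") {
          d <- log10(y[idx]) - log10(h[idx])
          scalings[g] <- 10^(sum(w * d) / sum(w))
        } else if (dist == "gaussian") {
          den <- sum(w * h[idx]^2)
          if (den == 0) stop("degenerate scaling group '", g, "'", call. = FALSE)
          scalings[g] <- sum(w * y[idx] * h[idx]) / den
        } else {
          nz <- h[idx] != 0
          if (!any(nz)) stop("degenerate scaling group '", g, "'", call. = FALSE)
          ww <- (abs(h[idx]) * sqrt(w))[nz]  # |h|/sigma
          scalings[g] <- weighted_lower_median((y[idx] / h[idx])[nz], ww)
        }
      } else if (sc == "log10") {
        scalings[g] <- log10_gaussian_inner(h[idx], y[idx])$s
      } else if (dist == "gaussian") {
        scalings[g] <- gaussian_inner(h[idx], y[idx])$s
      } else {
        s_hat <- laplace_inner_scaling(h[idx], y[idx])
        jump_points[[g]] <- attr(s_hat, "jump_points")
        scalings[g] <- as.numeric(s_hat)
      }
    }
    s_rec <- unname(scalings[m$scalingId])
    for (g in problem$free_noise_ids) {
      idx <- grp$by_noise[[g]]
      r <- residuals_on_scale(y[idx], h[idx], s_rec[idx], m$obs_scale[idx])
      noises[g] <- if (dist == "gaussian") sqrt(mean(r^2)) else mean(abs(r))
    }
    method <- if (dist == "laplace") "laplace_kinksearch"
      else if (all(m$obs_scale == "log10")) "log10_gaussian_analytic"
      else "gaussian_analytic"
  } else {
    cd <- inner_coordinate_descent(problem, h, grp, scalings, noises)
    scalings <- cd$scalings
    noises <- cd$noises
    iterations <- cd$iterations
    jump_points <- cd$jump_points
    method <- "coordinate_descent"
  }

  structure(list(scalings = scalings, noises = noises,
                 method_used = method,
                 jump_points = if (length(jump_points)) jump_points,
                 iterations = iterations, theta = theta, status = "ok"),
            class = "inner_solution")
}

# residuals on the scale each record is compared on
residuals_on_scale <- function(y, h, s, obs_scale) {
  r <- y - s * h
  lo <- obs_scale == "log10"
  if (any(lo)) r[lo] <- log10(y[lo]) - log10(s[lo] * h[lo])
  r
}

# coordinate descent for coupled scaling/noise sharing; closed-form blocks,
# monotone for Gaussian, guarded for Laplace
inner_coordinate_descent <- function(problem, h, grp, scalings, noises,
                                     tol = 1e-10, max_iter = 100L) {
  m <- problem$measurements
  y <- m$measurement
  dist <- problem$noise_distribution
  jump_points <- list()

  # initialization: unweighted per-group solutions, unit noise
  for (g in problem$free_scaling_ids) {
    idx <- grp$by_scaling[[g]]
    sc <- m$obs_scale[idx[1]]
    scalings[g] <- if (sc == "log10") log10_gaussian_inner(h[idx], y[idx])$s
      else if (dist == "gaussian") gaussian_inner(h[idx], y[idx])$s
      else {
        s0 <- laplace_inner_scaling(h[idx], y[idx])
        jump_points[[g]] <- attr(s0, "jump_points")
        as.numeric(s0)
      }
  }
  update_noises <- function(scalings, noises) {
    s_rec <- unname(scalings[m$scalingId])
    for (g in problem$free_noise_ids) {
      idx <- grp$by_noise[[g]]
      r <- residuals_on_scale(y[idx], h[idx], s_rec[idx], m$obs_scale[idx])
      noises[g] <- if (dist == "gaussian") sqrt(mean(r^2)) else mean(abs(r))
    }
    noises
  }
  objective <- function(scalings, noises) {
    nll_core(problem, h, NULL, scalings, noises, dist, want_grad = FALSE)$value
  }
  noises <- update_noises(scalings, noises)
  J <- objective(scalings, noises)

  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    sig_rec <- pmax(unname(noises[m$noiseId]), SIGMA_FLOOR)
    new_scalings <- scalings
    for (g in problem$free_scaling_ids) {
      idx <- grp$by_scaling[[g]]
      sc <- m$obs_scale[idx[1]]
      w <- 1 / sig_rec[idx]^2
      if (sc == "log10") {
        d <- log10(y[idx]) - log10(h[idx])
        new_scalings[g] <- 10^(sum(w * d) / sum(w))
      } else if (dist == "gaussian") {
        den <- sum(w * h[idx]^2)
        if (den == 0) stop("degenerate scaling group '", g, "'", call. = FALSE)
        new_scalings[g] <- sum(w * y[idx] * h[idx]) / den
      } else {
        nz <- h[idx] != 0
        if (!any(nz)) stop("degenerate scaling group '", g, "'", call. = FALSE)
        ww <- (abs(h[idx]) / sig_rec[idx])[nz]
        new_scalings[g] <- weighted_lower_median((y[idx] / h[idx])[nz], ww)
      }
    }
    new_noises <- update_noises(new_scalings, noises)
    J_new <- objective(new_scalings, new_noises)
    if (dist == "laplace" && J_new > J + 1e-12) {
      # guard: refine each scaling by 1-D minimization over its jump range
      for (g in problem$free_scaling_ids) {
        idx <- grp$by_scaling[[g]]
        nz <- h[idx] != 0
        rng <- range((y[idx] / h[idx])[nz])
        f <- function(s) {
          tmp <- new_scalings; tmp[g] <- s
          objective(tmp, update_noises(tmp, noises))
        }
        opt <- stats::optimize(f, lower = rng[1], upper = rng[2])
        if (opt$objective < J_new) {
          new_scalings[g] <- opt$minimum
          new_noises <- update_noises(new_scalings, noises)
          J_new <- objective(new_scalings, new_noises)
        }
      }
      if (J_new > J + 1e-12) break  # keep the previous (better) iterate
    }
    improved <- J - J_new
    scalings <- new_scalings
    noises <- new_noises
    J <- J_new
    if (is.finite(improved) && improved < tol) break
  }
  list(scalings = scalings, noises = noises, iterations = iterations,
       jump_points = jump_points)
}

#' @export
print.inner_solution <- function(x, ...) {
  cat("<inner_solution> method=", x$method_used,
      if (x$iterations > 0) paste0(", ", x$iterations, " iterations"), "\n",
      sep = "")
  cat("  s-hat:     ", paste(names(x$scalings), "=",
                             signif(x$scalings, 4), collapse = ", "), "\n")
  cat("  sigma-hat: ", paste(names(x$noises), "=",
                             signif(x$noises, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.inner_solution <- function(x, ...) {
  tibble::tibble(
    parameterId = c(names(x$scalings), names(x$noises)),
    type = rep(c("scaling", "noise"), c(length(x$scalings), length(x$noises))),
    estimate = c(unname(x$scalings), unname(x$noises)))
}
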