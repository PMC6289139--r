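# Negative log-likelihood machinery. One core routine evaluates J and its
# gradient blocks from per-record simulated observables; the exported
# gaussian_nll()/laplace_nll()/log10_gaussian_nll() and the hierarchical
# objective are thin layers over it. Densities use the natural log
# throughout; "log10" refers only to the observation scale and the
# optimizer's parameter transform.

SIGMA_FLOOR <- 1e-10
LN10 <- log(10)

# map records of a problem to simulated observable values / sensitivities
record_observables <- function(problem, sim) {
  m <- problem$measurements
  idx <- cbind(m$time_index, m$obs_index)
  h <- sim$observables[idx]
  hsens <- NULL
  if (!is.null(sim$observable_sensitivities)) {
    np <- dim(sim$observable_sensitivities)[3]
    hsens <- matrix(0, nrow(m), np)
    for (j in seq_len(np))
      hsens[, j] <- sim$observable_sensitivities[cbind(idx, j)]
  }
  list(h = h, hsens = hsens)
}

# full named scaling/noise vectors for a problem: free values supplied by the
# caller, fixed values from the structure
full_scaling_vector <- function(problem, scalings) {
  out <- c(scalings[problem$free_scaling_ids], problem$fixed_scalings)
  miss <- setdiff(problem$free_scaling_ids, names(scalings))
  if (length(miss) > 0)
    stop("missing scaling values for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out
}

full_noise_vector <- function(problem, noises) {
  out <- c(noises[problem$free_noise_ids], problem$fixed_noises)
  miss <- setdiff(problem$free_noise_ids, names(noises))
  if (length(miss) > 0)
    stop("missing noise values for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out
}

# J and gradient blocks given per-record simulated observables.
# h: vector over records; hsens: records x n_theta matrix or NULL.
# Returns value, grad_theta, grad_s / grad_sigma over the free groups,
# and flags. sigma == 0 is floored to SIGMA_FLOOR and flagged.
nll_core <- function(problem, h, hsens, s_full, sigma_full, distribution,
                     want_grad = TRUE) {
  m <- problem$measurements
  y <- m$measurement
  s_rec <- unname(s_full[m$scalingId])
  sig_rec <- unname(sigma_full[m$noiseId])
  if (any(sig_rec < 0)) stop("noise parameters must be >= 0", call. = FALSE)
  sigma_floored <- any(sig_rec < SIGMA_FLOOR)
  sig_rec <- pmax(sig_rec, SIGMA_FLOOR)

  n_theta <- problem$ode_model$n_dynamic
  grad_theta <- if (want_grad) numeric(n_theta)
  grad_s <- stats::setNames(numeric(length(problem$free_scaling_ids)),
                            problem$free_scaling_ids)
  grad_sigma <- stats::setNames(numeric(length(problem$free_noise_ids)),
                                problem$free_noise_ids)
  at_kink <- FALSE

  lin <- m$obs_scale == "linear"
  value <- 0

  # per-record contributions to the sigma gradient, accumulated by group
  dJ_dsig <- numeric(nrow(m))
  # per-record contributions to the s gradient
  dJ_ds <- numeric(nrow(m))

  if (any(lin)) {
    r <- y[lin] - s_rec[lin] * h[lin]
    sg <- sig_rec[lin]
    if (distribution == "gaussian") {
      value <- value + sum(0.5 * log(2 * pi * sg^2) + r^2 / (2 * sg^2))
      if (want_grad) {
        w <- r / sg^2                       # dJ/dr = -w per record
        dJ_ds[lin] <- -w * h[lin]
        dJ_dsig[lin] <- 1 / sg - r^2 / sg^3
        if (!is.null(hsens)) {
          coef <- -w * s_rec[lin]           # dJ/dh
          grad_theta <- grad_theta +
            colSums(hsens[lin, , drop = FALSE] * coef)
        }
      }
    } else { # laplace
      value <- value + sum(log(2 * sg) + abs(r) / sg)
      if (want_grad) {
        sgn <- sign(r)
        if (any(r == 0)) {
          # kink: resolve to the right-hand derivative in s
          at_kink <- TRUE
          k <- which(r == 0)
          sgn[k] <- -sign(h[lin][k])
        }
        dJ_ds[lin] <- -sgn * h[lin] / sg
        dJ_dsig[lin] <- 1 / sg - abs(r) / sg^2
        if (!is.null(hsens)) {
          coef <- -sgn * s_rec[lin] / sg
          grad_theta <- grad_theta +
            colSums(hsens[lin, , drop = FALSE] * coef)
        }
      }
    }
  }

  if (any(!lin)) {
    if (distribution != "gaussian")
      stop("log10 observation scale is only supported with gaussian noise",
           call. = FALSE)
    lo <- !lin
    sh <- s_rec[lo] * h[lo]
    if (any(sh <= 0) || any(!is.finite(sh))) {
      return(list(value = Inf, grad_theta = NULL, grad_s = NULL,
                  grad_sigma = NULL, at_kink = FALSE,
                  sigma_floored = sigma_floored, status = "nonpositive_observable"))
    }
    rl <- log10(y[lo]) - log10(sh)
    sg <- sig_rec[lo]
    value <- value + sum(0.5 * log(2 * pi * sg^2) + rl^2 / (2 * sg^2))
    if (want_grad) {
      w <- rl / sg^2
      dJ_ds[lo] <- -w / (s_rec[lo] * LN10)
      dJ_dsig[lo] <- 1 / sg - rl^2 / sg^3
      if (!is.null(hsens)) {
        coef <- -w / (h[lo] * LN10)
        grad_theta <- grad_theta + colSums(hsens[lo, , drop = FALSE] * coef)
      }
    }
  }

  if (want_grad) {
    if (length(grad_s) > 0) {
      agg <- rowsum(dJ_ds, m$scalingId)
      keep <- intersect(rownames(agg), names(grad_s))
      grad_s[keep] <- agg[keep, 1]
    }
    if (length(grad_sigma) > 0) {
      agg <- rowsum(dJ_dsig, m$noiseId)
      keep <- intersect(rownames(agg), names(grad_sigma))
      grad_sigma[keep] <- agg[keep, 1]
    }
  }

  list(value = value,
       grad_theta = if (want_grad) grad_theta,
       grad_s = if (want_grad) grad_s,
       grad_sigma = if (want_grad) grad_sigma,
       at_kink = at_kink, sigma_floored = sigma_floored, status = "ok")
}

objective_result <- function(value, gradient = NULL, n_residuals = 0L,
                             status = "ok", at_kink = FALSE,
                             sigma_floored = FALSE) {
  structure(list(value = value, gradient = gradient,
                 n_evaluated_residuals = as.integer(n_residuals),
                 status = status, at_kink = at_kink,
                 sigma_floored = sigma_floored),
            class = "objective_result")
}

#' @export
print.objective_result <- function(x, ...) {
  cat("<objective_result> J = ", format(x$value), " (", x$status, ")",
      if (x$at_kink) " [at kink]", if (x$sigma_floored) " [sigma floored]",
      "\n", sep = "")
  invisible(x)
}

# shared implementation of the standard (joint) objective
standard_nll <- function(problem, theta, scalings, noises, distribution,
                         gradient = TRUE) {
  stopifnot(inherits(problem, "estimation_problem"))
  s_full <- full_scaling_vector(problem, scalings)
  sigma_full <- full_noise_vector(problem, noises)
  if (any(sigma_full[problem$free_noise_ids] <= 0))
    stop("noise parameters must be strictly positive", call. = FALSE)
  sim <- simulate_model(problem$ode_model, problem$observation_model, theta,
                        problem$times, with_sensitivities = gradient)
  if (sim$status != "ok")
    return(objective_result(Inf, status = "solver_failure"))
  ro <- record_observables(problem, sim)
  core <- nll_core(problem, ro$h, ro$hsens, s_full, sigma_full, distribution,
                   want_grad = gradient)
  if (!is.finite(core$value))
    return(objective_result(Inf, status = core$status,
                            sigma_floored = core$sigma_floored))
  grad <- NULL
  if (gradient) {
    grad <- c(stats::setNames(core$grad_theta, problem$dynamic_ids),
              core$grad_s, core$grad_sigma)
  }
  objective_result(core$value, grad, nrow(problem$measurements),
                   status = "ok", at_kink = core$at_kink,
                   sigma_floored = core$sigma_floored)
}

#' Gaussian negative log-likelihood of the full parameter vector
#'
#' Evaluates \deqn{J(\theta, s, \sigma) = \sum_{i,k} \tfrac12 \log(2\pi\sigma^2)
#' + \frac{(\bar y_{i,k} - s\, h_i(x(t_k,\theta),\theta))^2}{2\sigma^2}}
#' with the group-resolved scaling and noise parameters, together with its
#' gradient over \eqn{(\theta, s, \sigma)} obtained via forward
#' sensitivities. Observables declared with `observation_scale = "log10"`
#' contribute Gaussian residuals on the log10 scale instead.
#'
#' @param problem an [build_problem()] result.
#' @param theta dynamic parameters (natural scale).
#' @param scalings named vector of values for the free scaling groups.
#' @param noises named vector of (strictly positive) values for the free
#'   noise groups.
#' @param gradient logical; also compute the gradient (requires forward
#'   sensitivities).
#' @return an `objective_result` with elements `value`, `gradient` (named
#'   over \eqn{(\theta, s, \sigma)}), `n_evaluated_residuals`, `status`.
#'   On integrator failure `value` is `+Inf` and `status` is
#'   `"solver_failure"`.
#' @export
gaussian_nll <- function(problem, theta, scalings, noises, gradient = TRUE) {
  standard_nll(problem, theta, scalings, noises, "gaussian", gradient)
}

#' Laplace negative log-likelihood of the full parameter vector
#'
#' Evaluates \deqn{J(\theta, s, \sigma) = \sum_{i,k} \log(2\sigma) +
#' \frac{|\bar y_{i,k} - s\, h_i(x(t_k,\theta),\theta)|}{\sigma}.}
#' The objective is continuous but not continuously differentiable; at a
#' kink (zero residual) the returned gradient uses the right-hand derivative
#' with respect to the scaling parameter and the result is flagged
#' (`at_kink = TRUE`), so gradient-based optimizers always receive a valid
#' subgradient element.
#'
#' @inheritParams gaussian_nll
#' @return an `objective_result`; see [gaussian_nll()].
#' @export
laplace_nll <- function(problem, theta, scalings, noises, gradient = TRUE) {
  standard_nll(problem, theta, scalings, noises, "laplace", gradient)
}

#' Gaussian negative log-likelihood on the log10 observation scale
#'
#' For observables compared on the log10 scale the residuals are
#' \eqn{\log_{10}\bar y_{i,k} - \log_{10}(s\, h_i)} and the Gaussian density
#' is applied to these log-residuals; the gradient carries the extra
#' \eqn{1/(h \ln 10)} chain-rule factor. All of the problem's observables
#' must be declared with `observation_scale = "log10"`; a non-positive
#' simulated observable at a measured time yields `value = +Inf` with a
#' diagnostic status, consistent with solver-failure handling.
#'
#' @inheritParams gaussian_nll
#' @return an `objective_result`; see [gaussian_nll()].
#' @export
log10_gaussian_nll <- function(problem, theta, scalings, noises,
                               gradient = TRUE) {
  if (!all(problem$measurements$obs_scale == "log10"))
    stop("log10_gaussian_nll() requires every observable on the log10 scale; ",
         "mixed-scale problems use gaussian_nll()", call. = FALSE)
  standard_nll(problem, theta, scalings, noises, "gaussian", gradient)
}
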