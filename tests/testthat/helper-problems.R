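# Shared fixtures and independent oracles, built in code at test time.

# tiny hand-built problem: exponential decay x' = -theta * x, one observable
decay_problem <- function(measurements, noise_distribution = "gaussian",
                          fixed_scaling = NULL, observation_scale = "linear") {
  model <- ode_model(
    name = "decay",
    rhs = function(t, x, theta) -theta[1] * x,
    initial_state = function(theta) 1,
    n_states = 1, n_dynamic = 1,
    state_names = "x", parameter_names = "kdec",
    jac_state = function(t, x, theta) matrix(-theta[1], 1, 1),
    jac_param = function(t, x, theta) matrix(-x[1], 1, 1),
    init_jac = function(theta) matrix(0, 1, 1))
  obs <- observation_model(function(x, theta) x, 1, "x",
                           observation_scale = observation_scale,
                           jac_state = function(x, theta) matrix(1, 1, 1),
                           jac_param = function(x, theta) matrix(0, 1, 1))
  str <- default_parameter_structure("kdec", "x",
                                     fixed_scalings = fixed_scaling)
  build_problem(model, obs, measurements, str, noise_distribution)
}

# independent per-record density product (Gaussian / Laplace), for checking
# exp(-J) against the likelihood definition
density_product <- function(y, yhat, sigma, distribution) {
  dens <- if (distribution == "gaussian")
    stats::dnorm(y, mean = yhat, sd = sigma)
  else 1 / (2 * sigma) * exp(-abs(y - yhat) / sigma)
  prod(dens)
}

# independent single-group objectives (written from the noise densities, not
# via the package's evaluators)
group_J_gaussian <- function(s, sigma, h, y)
  sum(0.5 * log(2 * pi * sigma^2) + (y - s * h)^2 / (2 * sigma^2))
group_J_laplace <- function(s, sigma, h, y)
  sum(log(2 * sigma) + abs(y - s * h) / sigma)
group_J_log10 <- function(s, sigma, h, y)
  sum(0.5 * log(2 * pi * sigma^2) + (log10(y) - log10(s * h))^2 / (2 * sigma^2))

# dense grid + Nelder-Mead refinement oracle for the one-group inner problem;
# s_positive restricts the grid to s > 0 (log10-scale objectives). The search
# domain is sigma >= sig_min: for groups the model fits exactly the objective
# is unbounded below as sigma -> 0, so analytic solution and oracle are
# compared on this common compact domain.
grid_refine_oracle <- function(J_fun, h, y, n_grid = 50, s_positive = FALSE,
                               sig_min = 1e-4) {
  J_safe <- function(s, sg) {
    sg <- max(sg, sig_min)
    v <- suppressWarnings(J_fun(s, sg, h, y))
    if (is.finite(v)) v else Inf
  }
  ratios <- y / h
  ratios <- ratios[is.finite(ratios)]
  s_lo <- min(ratios) - 0.5 * max(abs(ratios), 1)
  s_hi <- max(ratios) + 0.5 * max(abs(ratios), 1)
  if (s_positive) s_lo <- max(s_lo, 1e-6)
  s_grid <- seq(s_lo, s_hi, length.out = n_grid)
  sig_grid <- exp(seq(log(sig_min), log(10 * max(abs(y) + 1)),
                      length.out = n_grid))
  vals <- outer(s_grid, sig_grid, Vectorize(J_safe))
  best <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  p0 <- c(s_grid[best[1]], log(sig_grid[best[2]]))
  ref <- stats::optim(p0, function(p) J_safe(p[1], exp(p[2])),
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  min(vals[best[1], best[2]], ref$value)
}

# sorting-free weighted-median oracle: minimises sum(w * |x - m|) by direct
# evaluation at every candidate point
weighted_median_oracle <- function(x, w) {
  obj <- vapply(x, function(m) sum(w * abs(x - m)), numeric(1))
  cand <- x[obj == min(obj)]
  min(cand)  # lower median convention
}

# central finite differences of a scalar function
fd_grad <- function(f, at, h_rel = 1e-6) {
  vapply(seq_along(at), function(j) {
    h <- h_rel * max(abs(at[j]), 1)
    ap <- at; ap[j] <- at[j] + h
    am <- at; am[j] <- at[j] - h
    (f(ap) - f(am)) / (2 * h)
  }, numeric(1))
}

# random single-group inner-problem instances per configuration
random_inner_instance <- function(config, n = NULL) {
  n <- n %||% sample(1:50, 1)
  if (config == "log10_gaussian") {
    h <- stats::runif(n, 0.05, 3)
    y <- h * stats::runif(1, 0.5, 20) * 10^stats::rnorm(n, 0, 0.2)
  } else {
    h <- stats::runif(n, 0.05, 3)
    if (config == "laplace" && n > 2 && stats::runif(1) < 0.2)
      h[sample(n, 1)] <- 0  # records with h = 0 carry no jump point
    s_true <- stats::runif(1, 0.5, 5)
    noise <- if (config == "laplace")
      0.2 * (stats::rexp(n) - stats::rexp(n)) else stats::rnorm(n, 0, 0.2)
    y <- s_true * h + noise
  }
  list(h = h, y = y, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
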