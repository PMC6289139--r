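# The decay problem has h(t) = exp(-kdec * t); with kdec known the simulated
# observable is exact, so hand-computable objective values can be asserted.

decay_at <- function(times, k = 1) exp(-k * times)

test_that("gaussian objective reproduces hand-computed values", {
  # one record with ybar = s * h exactly and sigma = 1: J = log(2*pi)/2
  m <- tibble::tibble(observableId = "x", time = 1,
                      measurement = 2 * decay_at(1))
  pr <- decay_problem(m)
  r1 <- gaussian_nll(pr, 1, c(s_x = 2), c(sigma_x = 1))
  expect_equal(r1$value, 0.5 * log(2 * pi), tolerance = 1e-9)

  # two records with residuals +r and -r, sigma = 1: J = log(2*pi) + r^2
  r <- 0.3
  m2 <- tibble::tibble(observableId = "x", time = c(1, 2),
                       measurement = 2 * decay_at(c(1, 2)) + c(r, -r))
  pr2 <- decay_problem(m2)
  r2 <- gaussian_nll(pr2, 1, c(s_x = 2), c(sigma_x = 1))
  expect_equal(r2$value, log(2 * pi) + r^2, tolerance = 1e-7)
  expect_equal(r2$n_evaluated_residuals, 2L)
})

test_that("laplace objective reproduces hand-computed values and flags kinks", {
  # build a measurement equal to s times the *simulated* observable, so the
  # residual is exactly zero at the solver's own trajectory
  m_probe <- tibble::tibble(observableId = "x", time = 1, measurement = 1)
  pr_probe <- decay_problem(m_probe, noise_distribution = "laplace")
  h_sim <- simulate_model(pr_probe$ode_model, pr_probe$observation_model,
                          1, 1, with_sensitivities = TRUE)$observables[1, 1]
  m <- tibble::tibble(observableId = "x", time = 1, measurement = 2 * h_sim)
  pr <- decay_problem(m, noise_distribution = "laplace")
  r0 <- laplace_nll(pr, 1, c(s_x = 2), c(sigma_x = 1))
  expect_equal(r0$value, log(2), tolerance = 1e-9)
  expect_true(r0$at_kink)

  r <- 0.4
  m1 <- tibble::tibble(observableId = "x", time = 1,
                       measurement = 2 * decay_at(1) + r)
  pr1 <- decay_problem(m1, noise_distribution = "laplace")
  r1 <- laplace_nll(pr1, 1, c(s_x = 2), c(sigma_x = 1))
  expect_equal(r1$value, log(2) + r, tolerance = 1e-7)
  expect_false(r1$at_kink)
})

test_that("log10-scale objective is scale invariant and exact at zero residual", {
  m <- tibble::tibble(observableId = "x", time = c(1, 2),
                      measurement = 3 * decay_at(c(1, 2)))
  pr <- decay_problem(m, observation_scale = "log10")
  sg <- 0.2
  r <- log10_gaussian_nll(pr, 1, c(s_x = 3), c(sigma_x = sg))
  expect_equal(r$value, 2 * 0.5 * log(2 * pi * sg^2), tolerance = 1e-9)

  # doubling both measurements and the scaling leaves the value unchanged
  m2 <- m; m2$measurement <- 2 * m$measurement
  pr2 <- decay_problem(m2, observation_scale = "log10")
  r2 <- log10_gaussian_nll(pr2, 1, c(s_x = 6), c(sigma_x = sg))
  expect_equal(r2$value, r$value, tolerance = 1e-9)
})

test_that("exp(-J) equals the product of per-record densities", {
  set.seed(21)
  m <- tibble::tibble(observableId = "x", time = c(0.5, 1, 2, 3.5),
                      measurement = 2 * decay_at(c(0.5, 1, 2, 3.5)) +
                        rnorm(4, 0, 0.2))
  s <- 1.7; sg <- 0.25
  yhat <- s * decay_at(m$time)
  for (dist in c("gaussian", "laplace")) {
    pr <- decay_problem(m, noise_distribution = dist)
    fn <- if (dist == "gaussian") gaussian_nll else laplace_nll
    res <- fn(pr, 1, c(s_x = s), c(sigma_x = sg))
    expect_equal(exp(-res$value),
                 density_product(m$measurement, yhat, sg, dist),
                 tolerance = 1e-6)
  }
})

test_that("objective gradients match central finite differences", {
  set.seed(31)
  gen <- generate_problem(synthetic_spec("conversion_reaction", seed = 13,
                                         n_times = 6))
  pr <- gen$problem
  q0 <- c(0.9, 0.25, 1.4, 3.5, 0.2, 0.5)  # theta, s_A, s_B, sigma_A, sigma_B
  pack <- function(q) list(theta = q[1:2], s = c(s_A = q[3], s_B = q[4]),
                           sig = c(sigma_A = q[5], sigma_B = q[6]))
  for (dist in c("gaussian", "laplace")) {
    prd <- build_problem(pr$ode_model, pr$observation_model,
                         pr$measurements[1:12, 1:5], pr$structure, dist)
    fn <- if (dist == "gaussian") gaussian_nll else laplace_nll
    val <- function(q) {
      p <- pack(q)
      fn(prd, p$theta, p$s, p$sig, gradient = FALSE)$value
    }
    res <- fn(prd, pack(q0)$theta, pack(q0)$s, pack(q0)$sig)
    fd <- fd_grad(val, q0)
    expect_equal(unname(res$gradient), fd, tolerance = 1e-4)
  }
})

test_that("log10-scale gradient matches finite differences", {
  gen <- generate_problem(synthetic_spec("conversion_reaction", seed = 17,
                                         n_times = 6,
                                         observation_scale = "log10",
                                         noise_level = 0.1))
  pr <- gen$problem
  q0 <- c(0.7, 0.3, 2.1, 3.1, 0.15, 0.12)
  val <- function(q) log10_gaussian_nll(pr, q[1:2], c(s_A = q[3], s_B = q[4]),
                                        c(sigma_A = q[5], sigma_B = q[6]),
                                        gradient = FALSE)$value
  res <- log10_gaussian_nll(pr, q0[1:2], c(s_A = q0[3], s_B = q0[4]),
                            c(sigma_A = q0[5], sigma_B = q0[6]))
  expect_equal(unname(res$gradient), fd_grad(val, q0), tolerance = 1e-4)
})

test_that("gaussian objective is equivariant under joint rescaling", {
  set.seed(41)
  m <- tibble::tibble(observableId = "x", time = c(1, 2, 3),
                      measurement = c(0.9, 0.5, 0.4))
  c0 <- 3.7
  m2 <- m; m2$measurement <- c0 * m$measurement
  r1 <- gaussian_nll(decay_problem(m), 1, c(s_x = 1.2), c(sigma_x = 0.3),
                     gradient = FALSE)
  r2 <- gaussian_nll(decay_problem(m2), 1, c(s_x = c0 * 1.2),
                     c(sigma_x = c0 * 0.3), gradient = FALSE)
  expect_equal(r2$value, r1$value + 3 * log(c0), tolerance = 1e-9)
})

test_that("laplace objective is convex in the scaling parameter", {
  set.seed(51)
  m <- tibble::tibble(observableId = "x", time = seq(0.5, 4, length.out = 8),
                      measurement = runif(8, 0.1, 2))
  pr <- decay_problem(m, noise_distribution = "laplace")
  J_of_s <- function(s) laplace_nll(pr, 1, c(s_x = s), c(sigma_x = 0.4),
                                    gradient = FALSE)$value
  for (i in 1:20) {
    s1 <- runif(1, -2, 5); s2 <- runif(1, -2, 5)
    expect_lte(J_of_s((s1 + s2) / 2), (J_of_s(s1) + J_of_s(s2)) / 2 + 1e-10)
  }
})

test_that("simulation failure propagates as an infinite objective", {
  m <- tibble::tibble(observableId = "x", time = c(1, 5),
                      measurement = c(1, 2))
  model <- ode_model("blowup2", function(t, x, theta) theta[1] * x^2,
                     function(theta) 1, 1, 1, state_names = "x",
                     parameter_names = "kdec")
  obs <- observation_model(function(x, theta) x, 1, "x")
  str <- default_parameter_structure("kdec", "x")
  pr <- build_problem(model, obs, m, str)
  res <- gaussian_nll(pr, 100, c(s_x = 1), c(sigma_x = 1))
  expect_equal(res$value, Inf)
  expect_equal(res$status, "solver_failure")
  expect_null(res$gradient)
})

test_that("non-positive noise parameters are rejected", {
  m <- tibble::tibble(observableId = "x", time = 1, measurement = 1)
  pr <- decay_problem(m)
  expect_error(gaussian_nll(pr, 1, c(s_x = 1), c(sigma_x = 0)),
               "strictly positive")
  expect_error(gaussian_nll(pr, 1, c(s_x = 1), c(sigma_x = -1)),
               "strictly positive")
})
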