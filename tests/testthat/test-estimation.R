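cheap_problem <- function(seed = 7, dist = "gaussian") {
  generate_problem(synthetic_spec("conversion_reaction", seed = seed,
                                  n_times = 8,
                                  noise_distribution = dist))
}

test_that("hierarchical objective equals the joint objective at the inner optimum", {
  gen <- cheap_problem()
  pr <- gen$problem
  th <- unname(gen$ground_truth$theta)
  hier <- hierarchical_objective(pr, th)
  joint <- gaussian_nll(pr, th, hier$inner$scalings, hier$inner$noises)
  expect_equal(hier$value, joint$value, tolerance = 1e-12)
  # envelope gradient: theta block of the joint gradient
  expect_equal(hier$gradient,
               joint$gradient[pr$dynamic_ids], tolerance = 1e-10)
})

test_that("hierarchical objective is a pointwise lower envelope", {
  gen <- cheap_problem()
  pr <- gen$problem
  set.seed(123)
  for (i in 1:10) {
    th <- 10^runif(2, -1, 0.7)
    hv <- hierarchical_objective(pr, th, gradient = FALSE)$value
    s <- c(s_A = 10^runif(1, -1, 1), s_B = 10^runif(1, -1, 1))
    sg <- c(sigma_A = 10^runif(1, -2, 0.5), sigma_B = 10^runif(1, -2, 0.5))
    expect_lte(hv, gaussian_nll(pr, th, s, sg, gradient = FALSE)$value + 1e-10)
  }
})

test_that("hierarchical gradient matches finite differences (envelope theorem)", {
  gen <- cheap_problem()
  pr <- gen$problem
  set.seed(5)
  for (i in 1:3) {
    th <- 10^runif(2, -0.8, 0.6)
    g <- hierarchical_objective(pr, th)$gradient
    fd <- fd_grad(function(t)
      hierarchical_objective(pr, t, gradient = FALSE)$value, th)
    expect_equal(unname(g), fd, tolerance = 1e-3)
  }
})

test_that("converged fraction counts starts within the LR threshold", {
  expect_equal(converged_fraction(c(100.0, 100.05, 101.0, 105.0)), 0.75)
  expect_equal(converged_fraction(rep(42, 6)), 1)
  expect_equal(converged_fraction(c(1, 2, 3, 4), threshold = 0), 0.25)
  expect_equal(converged_fraction(c(5, Inf, Inf, Inf)), 0.25)
  expect_equal(lr_threshold(), qchisq(0.95, 1) / 2)
})

test_that("start-point sampling is seeded and matched across approaches", {
  gen <- cheap_problem()
  pr <- gen$problem
  a <- multistart_optimize(pr, "hierarchical", n_starts = 3, seed = 99,
                           optimizer_options = list(maxit = 5))
  b <- multistart_optimize(pr, "hierarchical", n_starts = 3, seed = 99,
                           optimizer_options = list(maxit = 5))
  expect_identical(a$starts$J0, b$starts$J0)
  expect_identical(a$starts$J, b$starts$J)
  # different seed gives different starts
  d <- multistart_optimize(pr, "hierarchical", n_starts = 3, seed = 100,
                           optimizer_options = list(maxit = 5))
  expect_false(identical(sort(a$starts$J0), sort(d$starts$J0)))
})

test_that("multistart results are sorted with the best start first", {
  gen <- cheap_problem()
  pr <- gen$problem
  ms <- multistart_optimize(pr, "hierarchical", n_starts = 6, seed = 2)
  expect_true(!is.unsorted(ms$starts$J))
  expect_equal(ms$best_J, ms$starts$J[1])
  expect_equal(ms$best_parameters, ms$starts$parameters[[1]])
  gl <- glance(ms)
  expect_gte(gl$converged_fraction, 0)
  expect_lte(gl$converged_fraction, 1)
  # reconstructed full parameter vector: theta plus all groups
  expect_named(ms$best_parameters, c("theta", "scalings", "noises"))
  expect_length(ms$best_parameters$scalings, 2)
})

test_that("a local optimization started at the truth descends", {
  gen <- cheap_problem()
  pr <- gen$problem
  th <- unname(gen$ground_truth$theta)
  J_true <- hierarchical_objective(pr, th, gradient = FALSE)$value
  fit <- optim(log10(th),
               function(p) hierarchical_objective(pr, 10^p,
                                                  gradient = FALSE)$value,
               function(p) {
                 r <- hierarchical_objective(pr, 10^p)
                 r$gradient * 10^p * log(10)
               },
               method = "L-BFGS-B", lower = c(-5, -5), upper = c(5, 5))
  expect_lte(fit$value, J_true + 1e-10)
})

test_that("the standard objective is stationary at the hierarchical optimum", {
  gen <- cheap_problem()
  pr <- gen$problem
  ms <- multistart_optimize(pr, "hierarchical", n_starts = 8, seed = 4)
  bp <- ms$best_parameters
  res <- gaussian_nll(pr, unname(bp$theta), bp$scalings, bp$noises)
  par_full <- c(bp$theta, bp$scalings[pr$free_scaling_ids],
                bp$noises[pr$free_noise_ids])
  # gradient on the optimizer (log10) scale, where the stopping rule lives
  g_opt <- res$gradient[names(par_full)] * par_full * log(10)
  expect_lt(max(abs(g_opt)), 1e-3)
})

test_that("comparison report has valid fractions and waterfall data", {
  gen <- cheap_problem()
  pr <- gen$problem
  cmp <- compare_approaches(pr, n_starts = 4, seed = 3,
                            optimizer_options = list(maxit = 100))
  expect_true(all(cmp$summary$converged_fraction >= 0 &
                    cmp$summary$converged_fraction <= 1))
  expect_named(cmp$waterfalls, c("standard", "hierarchical"))
  expect_true(all(vapply(cmp$waterfalls,
                         function(J) !is.unsorted(J[is.finite(J)]),
                         logical(1))))
  expect_s3_class(tidy(cmp), "tbl_df")
  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
})

test_that("laplace problems support the gradient-free fallback optimizer", {
  gen <- cheap_problem(dist = "laplace")
  pr <- gen$problem
  ms <- multistart_optimize(pr, "hierarchical", n_starts = 2, seed = 8,
                            optimizer_options = list(method = "Nelder-Mead",
                                                     maxit = 200))
  expect_true(any(is.finite(ms$starts$J)))
  expect_lte(ms$starts$J[1], ms$starts$J0[1])
})
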