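test_that("AR(1) covariance has the stated entries", {
  S <- ar1_covariance(2, error_model(0.25, 0.73))
  expect_equal(S, matrix(c(0.0625, 0.045625, 0.045625, 0.0625), 2))
  expect_equal(ar1_covariance(3, error_model(1, 0)), diag(3))
})

test_that("AR(1) precision matrix is tridiagonal", {
  P <- solve(ar1_covariance(4, error_model(0.25, 0.73)))
  off <- P[abs(row(P) - col(P)) > 1]
  expect_lt(max(abs(off)), 1e-12)
})

test_that("mean gradient matches central finite differences", {
  params <- calibrated(2)  # unshifted, 3 parameters
  t0 <- 50
  g <- drop(mean_gradient(t0, params, include_c = FALSE))
  num <- vapply(1:3, function(i) {
    h <- 1e-6 * abs(c(params$alpha, params$beta, params$t_scale)[i])
    shift <- function(s) {
      q <- params
      q[[c("alpha", "beta", "t_scale")[i]]] <- q[[c("alpha", "beta", "t_scale")[i]]] + s
      stats::dbeta(t0 / q$t_scale, q$alpha, q$beta)
    }
    (shift(h) - shift(-h)) / (2 * h)
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-5, ignore_attr = TRUE)

  params9 <- calibrated(9)  # shifted, 4 parameters
  g9 <- drop(mean_gradient(t0, params9, include_c = TRUE))
  num9 <- vapply(1:4, function(i) {
    nm <- c("alpha", "beta", "t_scale", "c")[i]
    h <- 1e-6 * max(abs(params9[[nm]]), 1)
    shift <- function(s) {
      q <- params9; q[[nm]] <- q[[nm]] + s
      stats::dbeta((t0 + q$c) / q$t_scale, q$alpha, q$beta)
    }
    (shift(h) - shift(-h)) / (2 * h)
  }, numeric(1))
  expect_equal(g9, num9, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("gradient is symmetric in the shapes at the midpoint", {
  params <- curve_parameters(3, 3, 400, 0)
  g <- drop(mean_gradient(200, params, include_c = FALSE))
  expect_equal(g[["alpha"]], g[["beta"]])
})

test_that("gradient errors at the unit-interval boundary", {
  params <- curve_parameters(2, 5, 100, 0)
  expect_error(mean_gradient(0, params, include_c = FALSE), "strictly inside")
  expect_error(mean_gradient(100, params, include_c = FALSE), "strictly inside")
})

test_that("Fisher information equals the explicit-loop oracle", {
  set.seed(42)
  err <- error_model(0.4, 0.6)
  params <- calibrated(9)
  for (rep in 1:5) {
    times <- sort(runif(4, 1, 300))
    FIM <- fisher_information(times, params, err)
    J <- mean_gradient(times, params, include_c = TRUE)
    Sinv <- solve(ar1_covariance(4, err))
    brute <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) for (k in 1:4) for (l in 1:4)
      brute[i, j] <- brute[i, j] + J[k, i] * Sinv[k, l] * J[l, j]
    expect_equal(FIM, brute, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("duplicated times make the information matrix singular", {
  params <- calibrated(1)
  FIM <- fisher_information(c(30, 30, 200), params, error_model())
  expect_equal(det(FIM), 0, tolerance = 1e-8 * max(abs(FIM))^3)
  expect_equal(d_objective(c(30, 30, 200), params, error_model()), 0)
  expect_equal(d_efficiency(c(30, 30, 200), c(0.3, 29.67, 183.83), params,
                            error_model()), 0)
})

test_that("information scales as 1/sigma^2", {
  params <- calibrated(1)
  times <- c(5, 50, 200)
  F1 <- fisher_information(times, params, error_model(1, 0.5))
  F2 <- fisher_information(times, params, error_model(0.5, 0.5))
  expect_equal(F2, 4 * F1, tolerance = 1e-12)
})

test_that("det(FIM) = det(J)^2 det(Sigma^-1) when samples = parameters", {
  set.seed(7)
  params <- calibrated(1)
  err <- error_model(0.25, 0.73)
  for (rep in 1:5) {
    times <- sort(runif(3, 1, 300))
    d1 <- det(fisher_information(times, params, err))
    J <- mean_gradient(times, params, include_c = FALSE)
    d2 <- det(J)^2 * det(solve(ar1_covariance(3, err)))
    expect_equal(d1, d2, tolerance = 1e-8)
  }
})

test_that("D-objective is zero for degenerate designs and negative otherwise", {
  params <- calibrated(1)
  err <- error_model()
  expect_equal(d_objective(c(10, 10, 10), params, err), 0)
  expect_lt(d_objective(c(0.3, 29.67, 183.83), params, err), 0)
  # the optimum is at least as good as the start design
  expect_lte(d_objective(c(0.3, 29.67, 183.83), params, err),
             d_objective(c(1, 30, 365), params, err))
})

test_that("D-efficiency is 1 at the reference and scale-free in sigma", {
  params <- calibrated(1)
  ref <- c(0.30, 29.67, 183.83)
  cand <- c(91.25, 182.5, 273.75)  # naive equidistant schedule
  expect_equal(d_efficiency(ref, ref, params, error_model()), 1)
  e1 <- d_efficiency(cand, ref, params, error_model(0.25, 0.73))
  e2 <- d_efficiency(cand, ref, params, error_model(2.5, 0.73))
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_gt(e1, 0)
  expect_lt(e1, 1)
})

test_that("d_objective agrees with the internal optimizer objective", {
  # regression guard: both paths must use det(FIM), not a transform of it
  for (id in c(1, 9)) {
    params <- calibrated(id)
    err <- error_model()
    np <- n_parameters(params)
    fn <- immunodesign:::make_design_objective(params, err, np)
    times <- seq(10, 300, length.out = np)
    expect_equal(fn(times), d_objective(times, params, err), tolerance = 1e-12)
  }
})

test_that("constructors validate the error model and design", {
  expect_error(error_model(0, 0.5), "sigma")
  expect_error(error_model(1, 1), "rho")
  expect_error(sampling_design(c(3, 2, 1)), "nondecreasing")
  expect_error(sampling_design(c(1, 2), lower = c(2, 0)), "lower")
})
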