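test_that("scenario presets match the study definitions", {
  tab <- scenario_table()
  expect_equal(nrow(tab), 12)
  expect_equal(tab$A0, rep(c(0, 1, 5), each = 4))
  expect_equal(tab$tmax, rep(c(30, 70), 6))
  expect_true(all(tab$Amax == 10))
  expect_true(all(tab$tplat == 365))
  expect_equal(tab$Aplat, rep(rep(c(1, 2.5), each = 2), 3))
  expect_error(scenario(13), "1..12")
})

test_that("misspecification ranges follow the stated rules", {
  expect_equal(misspecification_range(scenario(1), "tmax"), c(16, 44))
  expect_equal(misspecification_range(scenario(2), "tmax"), c(56, 84))
  expect_equal(misspecification_range(scenario(3), "Aplat"), c(0.5, 4.5))
  expect_equal(misspecification_range(scenario(1), "Aplat"), c(0, 3))
  expect_equal(misspecification_range(scenario(5), "A0"), c(0, 3))
  expect_equal(misspecification_range(scenario(9), "A0"), c(3, 7))
  expect_equal(misspecification_range(scenario(4), "Amax"), c(8, 12))
  expect_equal(misspecification_range(scenario(6), "tplat"), c(315, 415))
  expect_error(misspecification_range(scenario(1), "A0"), "not varied")
})

test_that("efficiency is one at the true value and failures never abort", {
  res <- sweep_single(scenario(1), "Amax", n_grid = 5)
  expect_s3_class(res, "robustness_result")
  # middle grid point is the true value: identical calibration, identical design
  expect_equal(res$efficiencies[3], 1, tolerance = 1e-4)
  expect_true(all(res$efficiencies[res$converged] >= 0 &
                  res$efficiencies[res$converged] <= 1))
  expect_equal(res$n_nonconverged, sum(!res$converged))
})

test_that("a zero plateau on the grid is recorded as non-converged", {
  res <- sweep_single(scenario(1), "Aplat", n_grid = 7)  # grid over [0, 3]
  expect_false(res$converged[1])
  expect_true(all(res$converged[-1]))
  expect_equal(res$n_nonconverged, 1)
})

test_that("misspecifying A0 to zero under a shifted truth drops out", {
  res <- sweep_single(scenario(5), "A0", n_grid = 7)  # grid over [0, 3]
  expect_false(res$converged[1])  # 3-point design cannot identify 4 parameters
})

test_that("deviations grow roughly linearly in misspecified tmax", {
  res <- sweep_single(scenario(1), "tmax", n_grid = 21)
  ok <- res$converged
  # central half of the converged grid, second sampling time
  idx <- which(ok)[abs(res$grid[ok] - 30) <= 7]
  fit <- lm(res$deviations[idx, 2] ~ res$grid[idx])
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("plateau-height misspecification mostly moves the last sample", {
  res <- sweep_single(scenario(1), "Aplat", n_grid = 21)
  for (k in c(2, 21)) {  # range endpoints (skipping the infeasible 0)
    if (!res$converged[k]) next
    dev <- abs(res$deviations[k, ])
    expect_lt(max(dev[1:2]), 0.2 * dev[3])
  }
})

test_that("double sweep covers the Cartesian grid and scores the true point 1", {
  # scenario 3's ranges ([16, 44] x [0.5, 4.5]) place the truth on a 3-point grid
  res <- sweep_double(scenario(3), n_grid_per_axis = 3)
  expect_equal(nrow(res$grid), 9)
  true_idx <- which(res$grid$tmax == 30 & res$grid$Aplat == 2.5)
  expect_equal(res$efficiencies[true_idx], 1, tolerance = 1e-4)
})

test_that("pooled summaries combine scenarios and track non-convergence", {
  r1 <- sweep_single(scenario(1), "Amax", n_grid = 5)
  r2 <- sweep_single(scenario(2), "Amax", n_grid = 5)
  pool <- summarize_pooled(list(r1, r2), by = "Amax")
  expect_equal(pool$n_runs, 10)
  expect_equal(pool$n_converged + pool$n_nonconverged, 10)
  expect_true(all(diff(pool$summary) >= 0))  # min <= q1 <= median <= q3 <= max
  expect_error(summarize_pooled(list(r1, sweep_single(scenario(1), "tplat", 3))),
               "different parameters")
  expect_error(summarize_pooled(list()), "empty")
})

test_that("pooled quartiles are stable to grid refinement", {
  r_coarse <- sweep_single(scenario(2), "Amax", n_grid = 11)
  r_fine <- sweep_single(scenario(2), "Amax", n_grid = 21)
  m1 <- median(r_coarse$efficiencies[r_coarse$converged])
  m2 <- median(r_fine$efficiencies[r_fine$converged])
  expect_lt(abs(m1 - m2), 0.01)
})
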