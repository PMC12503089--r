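test_that("beta density matches closed-form and quadrature values", {
  # 1/B(2,2) = 6, so f(0.5) = 6 * 0.25
  expect_equal(beta_density(0.5, 2, 2), 1.5)
  expect_equal(beta_density(0, 2, 5), 0)
  expect_equal(beta_density(1, 2, 5), 0)
  # frozen from quadrature of the unnormalized kernel x^0.24 (1-x)^14.81
  expect_equal(beta_density(0.3, 1.24, 15.81), 0.129651072224, tolerance = 1e-9)
})

test_that("beta density rejects out-of-domain input", {
  expect_error(beta_density(-0.1, 2, 2), "\\[0, 1\\]")
  expect_error(beta_density(1.1, 2, 2), "\\[0, 1\\]")
  expect_error(beta_density(0.5, 1, 2), "exceed 1")
  expect_error(beta_density(0.5, 2, 0.9), "exceed 1")
})

test_that("beta density integrates to one", {
  for (sh in list(c(2, 2), c(1.24, 15.81), c(2.23, 27.84))) {
    I <- integrate(beta_density, 0, 1, alpha = sh[1], beta = sh[2],
                   rel.tol = 1e-10)$value
    expect_equal(I, 1, tolerance = 1e-8)
  }
})

test_that("mode location is (alpha-1)/(alpha+beta-2)", {
  expect_equal(mode_location(2, 2), 0.5)
  expect_equal(mode_location(3, 2), 2 / 3)
  expect_equal(mode_location(1.24, 15.81), 0.24 / 15.05)
  expect_error(mode_location(1, 2), "exceed 1")
})

test_that("mean curve uses the plateau branch from tplat onwards", {
  info <- scen_info(1)
  params <- calibrated(1)
  expect_equal(mean_concentration(info$tplat, params, info), info$Aplat)
  expect_equal(mean_concentration(info$tplat + 100, params, info), info$Aplat)
  # half-open: just before the plateau the density branch applies
  expect_false(mean_concentration(info$tplat - 1e-6, params, info) == info$Aplat)
  # unshifted curve starts at zero
  expect_equal(mean_concentration(0, params, info), 0)
})

test_that("calibrated mean curve passes through the stated peak", {
  info <- scen_info(1)
  params <- calibrated(1)
  expect_equal(mean_concentration(info$tmax, params, info), info$Amax,
               tolerance = 1e-6)
})

test_that("mean curve is unimodal: rises to tmax, falls to tplat", {
  for (id in c(1, 9)) {
    info <- scen_info(id)
    params <- calibrated(id)
    up <- mean_concentration(seq(0, info$tmax, length.out = 400), params, info)
    down <- mean_concentration(seq(info$tmax, info$tplat - 1e-9, length.out = 400),
                               params, info)
    expect_true(all(diff(up) >= -1e-10))
    expect_true(all(diff(down) <= 1e-10))
  }
})

test_that("mode of the calibrated curve sits at tmax on the study time scale", {
  for (id in c(1, 9, 10)) {
    info <- scen_info(id)
    params <- calibrated(id)
    t_peak <- mode_location(params$alpha, params$beta) * params$t_scale - params$c
    expect_equal(t_peak, info$tmax, tolerance = 1e-6)
  }
})

test_that("initial information validates its invariants", {
  expect_error(initial_information(0, 400, 10, 365, 1), "tmax < tplat")
  expect_error(initial_information(0, 30, 10, 365, 12), "Aplat")
  expect_error(initial_information(11, 30, 10, 365, 1), "A0")
  expect_error(initial_information(-1, 30, 10, 365, 1), ">= 0")
  expect_s3_class(scen_info(5), "initial_information")
})

test_that("curve export writes a readable two-column CSV", {
  info <- scen_info(1)
  params <- calibrated(1)
  f <- withr::local_tempfile(fileext = ".csv")
  export_curve_csv(params, info, f, n = 11)
  df <- read.csv(f)
  expect_named(df, c("time", "mean"))
  expect_equal(nrow(df), 11)
  expect_equal(df$mean, mean_concentration(df$time, params, info))
})
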