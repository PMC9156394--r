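test_that("ols_fit agrees with the closed-form oracle to 1e-10", {
  cases <- list(
    list(x = diep_stagnation$angle_deg,
         y = diep_stagnation$max_stagnation_pct),
    list(x = c(1, 2, 3, 5, 8, 13), y = c(2.1, 3.9, 6.2, 9.8, 16.5, 25.9)),
    list(x = c(-2, 0, 1, 4), y = c(7, 3, 1.5, -4)))
  for (cs in cases) {
    fit <- ols_fit(cs$x, cs$y)
    oracle <- ols_oracle(cs$x, cs$y)
    expect_lt(abs(fit$slope - oracle$slope), 1e-10)
    expect_lt(abs(fit$intercept - oracle$intercept), 1e-10)
    expect_lt(abs(fit$r_squared - oracle$r_squared), 1e-10)
  }
})

test_that("exact linear data recovers the line with R^2 = 1", {
  x <- c(0, 1, 2, 3, 4)
  fit <- ols_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate inputs follow the stated conventions", {
  expect_warning(fit <- ols_fit(c(1, 2, 3), c(5, 5, 5)), "zero-variance")
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 0)
  expect_error(ols_fit(c(1, 2), c(1, 2, 3)), "same length")
  expect_error(ols_fit(c(2, 2, 2), c(1, 2, 3)), "distinct")
  expect_error(ols_fit(numeric(1), numeric(1)), "at least two")
})

test_that("r_squared is invariant under affine rescaling of the predictor", {
  x <- diep_stagnation$angle_deg; y <- diep_stagnation$max_stagnation_pct
  f1 <- ols_fit(x, y)
  f2 <- ols_fit(3 * x + 10, y)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(f2$slope, f1$slope / 3, tolerance = 1e-12)
})

test_that("prediction evaluates the fitted line", {
  fit <- fit_table3()
  expect_equal(predict(fit, 0), fit$intercept, tolerance = 1e-12)
  oracle <- ols_oracle(diep_stagnation$angle_deg,
                       diep_stagnation$max_stagnation_pct)
  expect_equal(predict(fit, 60), oracle$slope * 60 + oracle$intercept,
               tolerance = 1e-10)
  # residual check against the packaged 60-degree table value
  expect_lt(abs(predict(fit, 60) - 35.63), 1)
  flat <- suppressWarnings(ols_fit(c(1, 2, 3), c(4, 4, 4)))
  expect_equal(predict(flat, c(10, 100)), c(4, 4), tolerance = 1e-12)
})
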