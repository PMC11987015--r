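test_that("Davies log gamma matches hand-evaluated values and limits", {
  expect_identical(davies_log_gamma(0, 0.1), 0)
  expect_identical(davies_log_gamma(2, 0), 0)
  ## -0.51 * 4 * (sqrt(0.1)/(1+sqrt(0.1)) - 0.03) = -0.42890...
  expect_equal(davies_log_gamma(2, 0.1), -0.4289, tolerance = 1e-4)
  expect_error(davies_log_gamma(2, -0.1), "non-negative")
  expect_warning(davies_log_gamma(1, 0.7), "validity")
})

test_that("Davies coefficient is even in z and decreasing in |z|", {
  for (I in c(0.01, 0.1, 0.3)) {
    g <- davies_log_gamma(-3:3, I)
    expect_equal(g, rev(g))
    expect_true(all(diff(davies_log_gamma(0:4, I)) < 0))
  }
})

test_that("stepwise constants combine log-additively on the component basis", {
  expect_equal(stepwise_to_cumulative(list(list(type = "ML", logK = 11.48)))[["ML"]],
               11.48)
  zn <- stepwise_to_cumulative(list(list(type = "ML", logK = 11.48),
                                    list(type = "MLOH", logK = -9.69)))
  expect_equal(zn[["MLOH"]], 1.79)
  fe <- stepwise_to_cumulative(list(list(type = "ML", logK = 9.11),
                                    list(type = "MHL", logK = 6.20)))
  expect_equal(fe[["MHL"]], 15.31)
  expect_error(stepwise_to_cumulative(list(list(type = "MHL", logK = 6.2))),
               "require an ML entry")
  expect_error(stepwise_to_cumulative(list(list(type = "MLX", logK = 1))),
               "unknown reaction type")
})

test_that("conditional/intrinsic conversion follows the worked example and inverts", {
  ## Zn2+ + PDMA3- -> ZnPDMA-: delta z^2 = 1 - 4 - 9 = -12
  f015 <- sqrt(0.15) / (1 + sqrt(0.15)) - 0.3 * 0.15
  expect_equal(conditional_to_intrinsic(11.48, -12, 0.15),
               11.48 + 12 * 0.51 * f015)
  ## symmetric-charge reaction is unchanged
  expect_identical(conditional_to_intrinsic(5, 0, 0.3), 5)
  ## round trip to machine precision
  for (dz2 in c(-12, -6, 2)) {
    b0 <- conditional_to_intrinsic(11.48, dz2, 0.15)
    expect_equal(intrinsic_to_conditional(b0, dz2, 0.15), 11.48,
                 tolerance = 1e-12)
  }
})

test_that("Eh/pe conversion uses the Nernst factor", {
  expect_identical(eh_to_pe(0), 0)
  expect_equal(eh_to_pe(350, 298.15), 350 / 59.16, tolerance = 1e-3)
  expect_equal(eh_to_pe(-300, 298.15), -5.071, tolerance = 1e-3)
  expect_equal(pe_to_eh(eh_to_pe(123.4)), 123.4, tolerance = 1e-10)
  expect_error(eh_to_pe(100, T_K = -1))
})
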