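test_that("strong acid/base titration has the stoichiometric equivalence point", {
  proto <- titration_protocol(totals = numeric(0), acid_excess = 5e-3,
                              n_points = 80)
  cv <- simulate_titration(DB, proto)
  v_eq_true <- proto$V0 * 5e-3 / proto$base_conc
  ## steepest reading change brackets the equivalence volume
  i <- which.max(diff(cv$reading) / diff(cv$volume_mL))
  expect_equal(mean(cv$volume_mL[i + 0:1]), v_eq_true, tolerance = 0.02)
})

test_that("metal-free PDMA curve buffers at the published protonation constants", {
  proto <- titration_protocol()   # PDMA only
  cv <- simulate_titration(DB, proto)
  acid <- attr(cv, "acid_excess")
  L0 <- 6.7e-4
  ## titrable-proton ratio 1.5 on the L basis: midpoint of the second step
  v_mid2 <- proto$V0 * (acid - 1.5 * L0) / proto$base_conc
  pH_mid2 <- approx(cv$volume_mL, cv$reading, v_mid2)$y
  expect_equal(pH_mid2, 8.08, tolerance = 0.05)
  ## midpoint of the first (most basic) step; [OH-] shifts it slightly
  v_mid1 <- proto$V0 * (acid - 0.5 * L0) / proto$base_conc
  pH_mid1 <- approx(cv$volume_mL, cv$reading, v_mid1)$y
  expect_equal(pH_mid1, 10.32, tolerance = 0.35)
})

test_that("resampling the volume grid leaves the underlying curve unchanged", {
  proto <- titration_protocol(metal = "Zn", n_points = 40)
  cv <- simulate_titration(DB, proto)
  sub <- cv$volume_mL[seq(1, 40, by = 4)]
  cv2 <- simulate_titration(DB, proto, volumes = sub)
  expect_equal(cv2$reading, cv$reading[seq(1, 40, by = 4)],
               tolerance = 1e-9)
})

test_that("electrode calibration recovers E0 and slope", {
  proto <- titration_protocol(totals = numeric(0), acid_excess = 5e-3,
                              n_points = 60)
  cv <- simulate_titration(DB, proto, reading_kind = "emf")
  cal <- calibrate_electrode(cv, acid_conc = 5e-3)
  expect_equal(cal$E0, 400, tolerance = 1e-4)
  expect_equal(cal$slope, nernst_slope_mV(298.1), tolerance = 1e-4)
  expect_false(cal$non_nernstian)
  ## slope-fixed mode returns E0 only
  cal2 <- calibrate_electrode(cv, acid_conc = 5e-3,
                              slope_fixed = nernst_slope_mV(298.1))
  expect_equal(cal2$E0, 400, tolerance = 1e-4)
  expect_true(is.na(cal2$se_slope))
  ## Monte-Carlo recovery under reading noise (analytic fit, cheap)
  set.seed(11)
  e0s <- replicate(50, {
    noisy <- cv; noisy$reading <- noisy$reading + rnorm(nrow(cv), 0, 0.1)
    calibrate_electrode(noisy, acid_conc = 5e-3)$E0
  })
  expect_lt(max(abs(e0s - 400)), 0.2)
})

test_that("calibration demands acid-side points", {
  proto <- titration_protocol(totals = numeric(0), acid_excess = 5e-3,
                              n_points = 40, pH_window = c(8.5, 10))
  cv <- simulate_titration(DB, proto, reading_kind = "emf")
  expect_error(calibrate_electrode(cv, acid_conc = 5e-3),
               "insufficient acid-side")
})

test_that("noiseless refinement returns the generative constant from a perturbed start", {
  proto <- titration_protocol(metal = "Zn", n_points = 60)
  cv <- simulate_titration(DB, proto)
  ref <- refine_constants(DB, cv, "ZnPdma", start = c(ZnPdma = 12.48))
  expect_true(ref$converged)
  expect_equal(unname(ref$estimates[["ZnPdma"]]), 11.48, tolerance = 0.01)
  ## objective decreases monotonically over accepted steps (up to the
  ## numerical floor near convergence)
  expect_true(all(diff(ref$rsstrace) <= 1e-10 * max(ref$rsstrace)))
})

test_that("species absent from the data are flagged ill-conditioned, not refined", {
  proto <- titration_protocol(metal = "Zn", n_points = 40)
  cv <- simulate_titration(DB, proto)
  expect_warning(
    ref <- refine_constants(DB, cv, c("ZnPdma", "MgPdma"),
                            start = c(ZnPdma = 11.6, MgPdma = 4)),
    "ill-conditioned")
  expect_false("MgPdma" %in% names(ref$estimates))
  expect_equal(unname(ref$estimates[["ZnPdma"]]), 11.48, tolerance = 0.01)
})
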