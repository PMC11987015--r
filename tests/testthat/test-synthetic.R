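test_that("zero-noise replicates equal the noiseless simulation", {
  proto <- titration_protocol(metal = "Zn", n_points = 30)
  clean <- simulate_titration(DB, proto)
  reps <- make_titration_dataset(DB, proto,
                                 noise_model(sigma_reading = 0,
                                             sigma_volume = 0, seed = 3),
                                 replicates = 2)
  expect_length(reps, 2)
  for (cv in reps) expect_equal(cv$reading, clean$reading, tolerance = 1e-12)
})

test_that("generators are pure functions of inputs and seed", {
  proto <- titration_protocol(metal = "Zn", n_points = 25)
  nm <- noise_model(seed = 99)
  a <- make_titration_dataset(DB, proto, nm, replicates = 2)
  b <- make_titration_dataset(DB, proto, nm, replicates = 2)
  expect_identical(lapply(a, `[[`, "reading"), lapply(b, `[[`, "reading"))
  c1 <- make_soil_solution(suzuki_nutrient_solution(), 0.2, seed = 5)
  c2 <- make_soil_solution(suzuki_nutrient_solution(), 0.2, seed = 5)
  expect_identical(c1, c2)
  expect_false(identical(c1, make_soil_solution(suzuki_nutrient_solution(),
                                                0.2, seed = 6)))
  expect_identical(make_soil_solution(suzuki_nutrient_solution(), 0),
                   suzuki_nutrient_solution())
  ## jitter stays within the declared multiplicative band
  expect_true(all(c1 / suzuki_nutrient_solution() > 0.8 &
                    c1 / suzuki_nutrient_solution() < 1.2))
})

test_that("the global RNG stream is not disturbed by the generators", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(make_soil_solution(suzuki_nutrient_solution(), 0.1, seed = 42))
  expect_identical(runif(1), before)
})

test_that("jittered nutrient solutions preserve the reducing-condition Zn selectivity", {
  ## robustness of the headline qualitative claim to composition uncertainty
  ok <- 0L
  for (k in 1:6) {
    base <- suzuki_nutrient_solution(jitter_fraction = 0.2, seed = k)
    tot <- c(base, nacl(0.1))
    shares <- vapply(c(6, 8, 10), function(pH) {
      r <- solve_equilibrium(DB, solution_spec(tot, pH = pH,
                                               pe = eh_to_pe(-300), I = 0.1,
                                               allow_solids = TRUE))
      pool <- vapply(c("Zn", "Fe3", "Cu", "Mn", "Mg"), function(m)
        pdmaspec:::complex_conc(r, m, "Pdma", one_to_one = TRUE), numeric(1))
      pool[["Zn"]] / sum(pool)
    }, numeric(1))
    if (all(shares > 0.95)) ok <- ok + 1L
  }
  expect_gte(ok, 5L)
})
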