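test_that("Newton solver agrees with the nested-bisection oracle", {
  worst <- 0
  pred <- obs <- numeric(0)
  for (s in random_ml_specs(25)) {
    r1 <- solve_equilibrium(DB, s)
    r2 <- brute_force_oracle(DB, s)
    cm <- intersect(r1$species$species, r2$species$species)
    c1 <- r1$species$concentration[match(cm, r1$species$species)]
    c2 <- r2$species$concentration[match(cm, r2$species$species)]
    sel <- c2 > 1e-25
    worst <- max(worst, max(abs(c1[sel] - c2[sel]) / c2[sel]))
    pred <- c(pred, log10(c1[sel])); obs <- c(obs, log10(c2[sel]))
  }
  expect_lt(worst, 1e-6)
  fit <- stats::lm(pred ~ obs)
  expect_gte(unname(stats::coef(fit)[2]), 0.99)
  expect_gte(summary(fit)$r.squared, 0.99)
})

test_that("oracle refuses more than two free components", {
  s <- solution_spec(c(Zn = 1e-6, Cu = 1e-6, Pdma = 1e-5, nacl(0.1)),
                     pH = 6, I = 0.1)
  expect_error(brute_force_oracle(DB, s), "at most 2")
})

test_that("single protonation equilibrium reproduces the Henderson-Hasselbalch point", {
  ## at pH = conditional pKa1 the first protonation is half complete
  I <- 0.1
  pka1 <- cond_at(DB, "HPdma", I) - davies_log_gamma(1, I)  # activity pH
  s <- solution_spec(c(Pdma = 1e-4), pH = pka1, I = I)
  r <- brute_force_oracle(DB, s)
  fr <- r$fractions[r$fractions$component == "Pdma", ]
  expect_equal(fr$fraction[fr$species == "HPdma"], 0.5, tolerance = 0.02)
})
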