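test_that("no-ligand limit: free metal equals its total at mildly acidic pH", {
  ## inert-medium run (no chloride in the totals): hydrolysis is negligible
  s <- solution_spec(c(Zn = 1e-6), pH = 5, I = 0.1)
  r <- solve_equilibrium(DB, s)
  expect_true(r$converged)
  expect_equal(unname(r$free[["Zn"]]) / 1e-6, 1, tolerance = 1e-2)
})

test_that("converged results satisfy mass balance and fraction closure", {
  specs <- c(random_ml_specs(8),
             list(solution_spec(c(Zn = 1e-6, Cu = 1e-6, Fe3 = 1e-6,
                                  Pdma = 1e-5, nacl(0.1)),
                                pH = 7, pe = eh_to_pe(350), I = 0.1,
                                allow_solids = TRUE)))
  for (s in specs) {
    r <- solve_equilibrium(DB, s)
    expect_true(r$converged)
    expect_lt(max(abs(r$residuals)), 1e-8)
    sums <- tapply(r$fractions$fraction, r$fractions$component, sum)
    expect_lt(max(abs(as.numeric(sums) - 1)), 1e-8)
  }
})

test_that("Zn-PDMA fraction at pH 7 matches the side-reaction-coefficient closed form", {
  I <- 0.1
  s <- solution_spec(c(Zn = 1e-6, Pdma = 1e-5, nacl(I)), pH = 7, I = I)
  r <- solve_equilibrium(DB, s)
  frac <- fraction_complexed(r, "Zn", "Pdma")
  ## independent closed form: alpha_L(H) from the cumulative protonation
  ## constants, K' = beta_ZnL / alpha, fraction = K'[L']/(1 + K'[L'])
  h <- 10^(-7) / 10^davies_log_gamma(1, I)
  lb <- vapply(c("HPdma", "H2Pdma", "H3Pdma", "H4Pdma", "H5Pdma"),
               function(x) cond_at(DB, x, I), numeric(1))
  alpha <- 1 + sum(10^lb * h^(1:5))
  ## Zn side reactions (chloride, hydroxide) at pH 7 / I 0.1 are < 1%
  kp <- 10^(cond_at(DB, "ZnPdma", I)) / alpha
  Lfree <- (1e-5 - frac * 1e-6)          # ligand not bound to Zn
  pred <- kp * Lfree / (1 + kp * Lfree)
  expect_equal(frac, pred, tolerance = 0.02)
  expect_gt(frac, 0.98)
})

test_that("fraction and selectivity edge cases behave per contract", {
  s <- solution_spec(c(Zn = 1e-6, Mg = 1e-6, Pdma = 1e-5, nacl(0.1)),
                     pH = 8, I = 0.1)
  r <- solve_equilibrium(DB, s)
  expect_identical(fraction_complexed(r, "Zn", "Cit"), 0)  # no shared species
  expect_equal(fraction_complexed(r, "Zn", "Pdma"), 1, tolerance = 1e-3)
  expect_error(fraction_complexed(r, "Ni", "Pdma"), "zero")
  lsZn <- selectivity_log_S(r, "Zn")      # metal == reference
  expect_equal(lsZn, 0)
  expect_lt(selectivity_log_S(r, "Mg"), 0)
  ## zero reference pool: -Inf sentinel, no error
  s2 <- solution_spec(c(Mg = 1e-6, Pdma = 1e-5, nacl(0.1)), pH = 8, I = 0.1)
  r2 <- solve_equilibrium(DB, s2)
  v <- selectivity_log_S(r2, "Mg", reference = "Zn")
  expect_identical(as.numeric(v), -Inf)
  expect_true(attr(v, "zero_reference"))
})

test_that("invalid inputs raise immediately", {
  expect_error(solution_spec(c(Zn = -1e-6), pH = 7), "negative total")
  expect_error(solution_spec(c(Zn = 1e-6), pH = 7, I = 0), "positive")
  expect_error(solve_equilibrium(DB, solution_spec(c(Zn = 0, Pdma = 0),
                                                   pH = 7, I = 0.1)),
               "all totals are zero")
})

test_that("pH sweep of Zn-PDMA is monotone before the hydroxo region", {
  s <- solution_spec(c(Zn = 1e-6, Pdma = 1e-5, nacl(0.1)), pH = 3, I = 0.1)
  grid <- seq(3, 8, by = 0.25)
  tab <- sweep_axis(DB, s, "pH", grid)
  res <- attr(tab, "results")
  fr <- vapply(res, fraction_complexed, numeric(1), metal = "Zn",
               ligand = "Pdma")
  expect_true(all(diff(fr) > -1e-9))
  ## single-point grid reduces to a plain solve
  one <- sweep_axis(DB, s, "pH", 6.5)
  direct <- solve_equilibrium(DB, solution_spec(c(Zn = 1e-6, Pdma = 1e-5,
                                                  nacl(0.1)),
                                                pH = 6.5, I = 0.1))
  f1 <- one[one$component == "Zn" & one$species == "ZnPdma", "fraction"]
  f2 <- direct$fractions[direct$fractions$component == "Zn" &
                           direct$fractions$species == "ZnPdma", "fraction"]
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("half-complexation pH shifts to higher pH with ionic strength", {
  half_pH <- function(I) {
    s <- solution_spec(c(Zn = 1e-6, Pdma = 1e-5, nacl(I)), pH = 3, I = I)
    grid <- seq(4, 9, by = 0.05)
    res <- attr(sweep_axis(DB, s, "pH", grid), "results")
    fr <- vapply(res, fraction_complexed, numeric(1), metal = "Zn",
                 ligand = "Pdma")
    grid[which.min(abs(fr - 0.5))]
  }
  h <- suppressWarnings(vapply(c(0.02, 0.1, 0.7), half_pH, numeric(1)))
  expect_true(all(diff(h) > 0))
})

test_that("supersaturated ferric iron precipitates to SI = 0 with closed mass balance", {
  s <- solution_spec(c(Fe3 = 1e-5, nacl(0.1)), pH = 7, pe = eh_to_pe(350),
                     I = 0.1, allow_solids = TRUE)
  r <- solve_equilibrium(DB, s)
  sol <- r$solids[r$solids$solid == "Ferrihydrite", ]
  expect_true(sol$active)
  expect_equal(sol$SI, 0, tolerance = 1e-8)
  expect_gt(sol$amount, 0.9e-5)
  expect_lt(max(abs(r$residuals)), 1e-8)
  ## the same system without solids is reported supersaturated
  s2 <- s; s2$allow_solids <- FALSE
  r2 <- solve_equilibrium(DB, s2)
  expect_null(r2$solids)
})

test_that("fixed Eh with no redox-active metals matches the redox-free run", {
  tot <- c(Zn = 1e-6, Pdma = 1e-5, nacl(0.1))
  r1 <- solve_equilibrium(DB, solution_spec(tot, pH = 6, I = 0.1))
  r2 <- solve_equilibrium(DB, solution_spec(tot, pH = 6, pe = eh_to_pe(350),
                                            I = 0.1))
  expect_equal(fraction_complexed(r1, "Zn", "Pdma"),
               fraction_complexed(r2, "Zn", "Pdma"), tolerance = 1e-10)
})

test_that("redox split follows Eh: ferric above neutrality oxidizing, ferrous reducing", {
  for (pH in c(7, 8, 9)) {
    r_ox <- solve_equilibrium(DB, solution_spec(
      c(Fe3 = 1e-6, Pdma = 1e-5, nacl(0.1)), pH = pH,
      pe = eh_to_pe(350), I = 0.1, allow_solids = TRUE))
    sp_ox <- pdmaspec:::redox_split(r_ox, "Fe3")
    expect_lt(sp_ox[["reduced"]], 0.05)
    r_red <- solve_equilibrium(DB, solution_spec(
      c(Fe3 = 1e-6, Pdma = 1e-5, nacl(0.1)), pH = pH,
      pe = eh_to_pe(-300), I = 0.1, allow_solids = TRUE))
    sp_red <- pdmaspec:::redox_split(r_red, "Fe3")
    expect_lt(sp_red[["oxidized"]] + sp_red[["solid"]], 0.05)
  }
})
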