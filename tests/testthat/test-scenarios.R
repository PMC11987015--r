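cfgI <- scenario_config("ionic_strength", pH_grid = seq(3, 9, by = 0.25),
                        I_set = c(0.02, 0.1, 0.7), ligands = "Pdma",
                        mixed = FALSE)

test_that("ionic-strength scenario: quantitative Zn complexation and salt shift", {
  rep <- suppressWarnings(run_ionic_strength(DB, cfgI))
  r <- rep$report
  ## low salt: quantitative complexation at pH 7
  expect_gte(r$value[r$I == 0.02 & r$pH == 7], 0.99)
  ## the half-complexation pH moves up with ionic strength (interpolated)
  half <- vapply(c(0.02, 0.1, 0.7), function(I) {
    sub <- r[r$I == I, ]
    sub <- sub[order(sub$pH), ]
    stats::approx(sub$value, sub$pH, 0.5, ties = "ordered")$y
  }, numeric(1))
  expect_true(all(diff(half) > 0))
  ## a single-I degenerate config is a plain sweep
  one <- suppressWarnings(run_ionic_strength(
    DB, scenario_config("ionic_strength", pH_grid = c(5, 6, 7),
                        I_set = 0.1, ligands = "Pdma")))
  s <- solution_spec(c(Zn = 1e-6, Pdma = 1e-5, nacl(0.1)), pH = 6, I = 0.1)
  direct <- fraction_complexed(solve_equilibrium(DB, s), "Zn", "Pdma")
  expect_equal(one$report$value[one$report$pH == 6], direct,
               tolerance = 1e-9)
})

test_that("missing competing-ligand constants raise an explicit error", {
  db2 <- DB
  keep <- !vapply(db2$species$stoich, function(s) "Dma" %in% names(s),
                  logical(1))
  db2$species <- db2$species[keep, ]
  expect_error(run_ionic_strength(
    db2, scenario_config("ionic_strength", I_set = 0.1, ligands = "Dma")),
    "constants")
})

test_that("redox scenario: Cu complexation falls with ionic strength at pH 3", {
  cfg <- scenario_config("redox", pH_grid = c(3, 4.5),
                         Eh_set = 350, I_set = c(0.02, 0.1, 0.7),
                         metals = "Cu")
  rep <- suppressWarnings(run_redox(DB, cfg))
  r <- rep$report
  at3 <- r[r$pH == 3 & r$quantity == "fraction", ]
  expect_true(all(diff(at3$value[order(at3$I)]) < 0))
  ## reducing conditions: no ferric-PDMA complex forms
  cfgF <- scenario_config("redox", pH_grid = seq(3, 9, by = 0.5),
                          Eh_set = -300, I_set = 0.1, metals = "Fe3")
  repF <- run_redox(DB, cfgF)
  ox <- subset(repF$report, quantity == "complex_oxidized")
  expect_lt(max(ox$value), 1e-6)
})

test_that("metal competition: Mn and Mg never compete with Zn; Cu inert when reduced", {
  cfg <- scenario_config("metal_competition", pH_grid = seq(3, 9, by = 0.5))
  rep <- run_metal_competition(DB, cfg)
  r <- rep$report
  ls <- r[r$quantity == "logS" & r$metal %in% c("Mn", "Mg"), ]
  expect_true(all(ls$value < 0))
  ## reducing, acidic side: copper is Cu(I) and forms no PDMA complex
  cu_red <- r[r$metal == "Cu" & r$Eh_mV == -300 & r$pH <= 6 &
                r$quantity == "fraction", ]
  expect_lt(max(cu_red$value), 0.01)
  ## oxidizing: iron ends up precipitated at alkaline pH
  fe_ox <- r[r$metal == "Fe3" & r$Eh_mV == 350 & r$pH == 9 &
               r$quantity == "fraction", ]
  expect_lt(max(fe_ox$value), 0.5)
})

test_that("ligand competition: PDMA beats citrate and DFOB for Zn in the mixed run", {
  cfg <- scenario_config("ligand_competition", pH_grid = seq(4, 9, by = 0.5),
                         I_set = 0.02, competitor = "Cit")
  rep <- run_ligand_competition(DB, cfg)
  r <- rep$report
  mixed_pdma <- r[r$quantity == "fraction_mixed" & r$ligand == "Pdma" &
                    r$pH >= 8, ]
  expect_true(all(mixed_pdma$value >= 0.95))
  ## citrate takes part of the weakly acidic window in the single run
  single_cit <- r[r$quantity == "fraction_single_comp" & r$ligand == "Cit", ]
  expect_gt(max(single_cit$value), 0.2)
  ## DFOB (log K 9.91 < 11.48) does not out-compete PDMA
  cfgD <- scenario_config("ligand_competition", pH_grid = c(7, 8, 9),
                          I_set = 0.02, competitor = "Dfob")
  repD <- run_ligand_competition(DB, cfgD)
  rd <- repD$report
  expect_true(all(rd$value[rd$quantity == "fraction_mixed" &
                             rd$ligand == "Pdma"] >
                    rd$value[rd$quantity == "fraction_mixed" &
                               rd$ligand == "Dfob"]))
  ## zero competitor reduces to the single-ligand run
  cfg0 <- scenario_config("ligand_competition", pH_grid = c(6, 7),
                          I_set = 0.1, competitor = "Cit",
                          competitor_total = 0)
  rep0 <- run_ligand_competition(DB, cfg0)
  r0 <- rep0$report
  expect_equal(r0$value[r0$quantity == "fraction_mixed" & r0$ligand == "Pdma"],
               r0$value[r0$quantity == "fraction_single_pdma"],
               tolerance = 1e-9)
  expect_error(run_ligand_competition(
    DB, scenario_config("ligand_competition", competitor = "Humic")),
    "available")
})

test_that("soil solution: reducing conditions hand the ligand to zinc", {
  cfg <- scenario_config("soil_solution", pH_grid = seq(3, 10, by = 0.5),
                         pdma_total = 2.5e-7)
  rep <- run_soil_solution(DB, cfg)
  r <- rep$report
  red <- r[r$Eh_mV == -300 & r$metal == "Zn" & r$quantity == "pdma_share" &
             r$pH >= 6, ]
  expect_true(all(red$value >= 0.99))
  ls <- r[r$Eh_mV == -300 & r$quantity == "logS" & r$pH >= 6, ]
  expect_true(all(ls$value < 0))
  ## oxidizing: copper complexes PDMA over a wide pH window
  cu <- r[r$Eh_mV == 350 & r$metal == "Cu" & r$quantity == "pdma_share" &
            r$pH >= 4 & r$pH <= 9, ]
  expect_true(all(cu$value > 0.2))
  ## identical configs give identical reports (determinism)
  rep2 <- run_soil_solution(DB, cfg)
  expect_identical(rep$report, rep2$report)
  ## EDTA removal is an explicit error
  db2 <- DB
  keep <- !vapply(db2$species$stoich, function(s) "Edta" %in% names(s),
                  logical(1))
  db2$species <- db2$species[keep, ]
  expect_error(run_soil_solution(db2, cfg), "EDTA")
})

test_that("excess grids: competitor-free limit and ratio validation", {
  cfg <- scenario_config("excess_grid", part = "a", ratios_a = c(1e-6, 10),
                         pH_set = 7, Eh_set = 350)
  rep <- run_excess_grid(DB, cfg)
  r <- rep$report
  ## vanishing competitor: no reduction of the Zn-PDMA pool
  expect_lt(abs(r$value[r$ratio == 1e-6 & r$metal == "Cu"]), 0.5)
  expect_gt(r$value[r$ratio == 10 & r$metal == "Cu"], 99)
  expect_error(run_excess_grid(DB, scenario_config(
    "excess_grid", part = "a", ratios_a = c(-1, 2), pH_set = 7)),
    "positive")
})
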