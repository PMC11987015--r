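#!/usr/bin/env Rscript
# Redox control of Cu- and Fe-PDMA complexation.
#
# Single-metal systems (M 1e-6, PDMA 1e-5 mol/dm^3) swept over pH at
# Eh = -300 and +350 mV and three ionic strengths, with the Cu(II)/Cu(I)
# and Fe(III)/Fe(II) couples and ferric-oxide precipitation active.

suppressPackageStartupMessages(library(pdmaspec))
dir.create("results", showWarnings = FALSE)
db <- pdma_database()

cfg <- scenario_config("redox", pH_grid = seq(3, 9, by = 0.1),
                       Eh_set = c(-300, 350), I_set = c(0.02, 0.1, 0.7),
                       metals = c("Cu", "Fe3"))
rep <- suppressWarnings(run_redox(db, cfg))
write.csv(rep$report, "results/redox.csv", row.names = FALSE)
write_run_manifest("03_redox", "results/redox.csv", db)

r <- rep$report
cu3 <- subset(r, metal == "Cu" & Eh_mV == 350 & pH == 3 &
                quantity == "fraction")
cat("Oxidizing Cu-PDMA at pH 3 (% of Cu), I = 0.02/0.1/0.7:",
    paste(round(100 * cu3$value[order(cu3$I)], 1), collapse = " / "), "\n")
fe_red <- subset(r, metal == "Fe3" & Eh_mV == -300 & I == 0.1 &
                   quantity == "complex_oxidized")
cat("Reducing conditions: max ferric-PDMA fraction =",
    signif(max(fe_red$value), 2),
    "(iron stays ferrous; no Fe(III) complex forms).\n")
fe_ox <- subset(r, metal == "Fe3" & Eh_mV == 350 & I == 0.1 &
                  quantity == "fraction_solid")
cat("Oxidizing conditions: iron precipitates as ferric oxide above ~pH",
    min(fe_ox$pH[fe_ox$value > 0.5]), "\n")
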