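#' Configure a computational speciation experiment
#'
#' Shared configuration for the scripted experiments: grids of pH, redox
#' potential and ionic strength over the standard trace-metal/ligand
#' working concentrations (metal 1e-6, ligand 1e-5 mol/dm^3 unless a
#' scenario states otherwise).
#'
#' @param kind one of `"ionic_strength"`, `"redox"`, `"metal_competition"`,
#'   `"ligand_competition"`, `"soil_solution"`, `"excess_grid"`.
#' @param pH_grid sorted pH grid.
#' @param Eh_set redox potentials, mV.
#' @param I_set ionic strengths (NaCl), mol/dm^3.
#' @param metal_total,ligand_total working concentrations, mol/dm^3.
#' @param ... scenario-specific fields kept in the config.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(kind, pH_grid = seq(3, 9, by = 0.1),
                            Eh_set = c(-300, 350), I_set = 0.1,
                            metal_total = 1e-6, ligand_total = 1e-5, ...) {
  kinds <- c("ionic_strength", "redox", "metal_competition",
             "ligand_competition", "soil_solution", "excess_grid")
  if (!kind %in% kinds)
    stop("unknown scenario kind; available: ", paste(kinds, collapse = ", "))
  structure(c(list(kind = kind, pH_grid = pH_grid, Eh_set = Eh_set,
                   I_set = I_set, metal_total = metal_total,
                   ligand_total = ligand_total), list(...)),
            class = "scenario_config")
}

.check_ligand <- function(db, ligand) {
  if (!ligand %in% db$components$name ||
      !any(vapply(db$species$stoich, function(s) ligand %in% names(s),
                  logical(1))))
    stop("no constants for ligand '", ligand,
         "' in the database; supply them via the constants CSV ",
         "(see write_database)")
}

.report <- function(config, rows) {
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  structure(list(report = rep, config = config),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report '%s': %d rows>\n", x$config$kind,
              nrow(x$report)))
  print(utils::head(x$report, 10), row.names = FALSE)
  invisible(x)
}

# concentration summed over complexes of `metal` with `ligand`; `reduced`
# restricts to electron-bearing (TRUE) or electron-free (FALSE) species;
# `one_to_one` keeps only the plain ML complexes (no MHL/MLOH forms).
complex_conc <- function(result, metal, ligand, reduced = NA,
                         one_to_one = FALSE) {
  if (!metal %in% colnames(result$A) || !ligand %in% colnames(result$A))
    return(0)
  sel <- result$A[, metal] > 0 & result$A[, ligand] > 0
  if (!is.na(reduced) && "e" %in% colnames(result$A))
    sel <- sel & ((result$A[, "e"] > 0) == reduced)
  if (one_to_one && "H" %in% colnames(result$A))
    sel <- sel & result$A[, "H"] == 0
  sum(result$species$concentration[sel])
}

# dissolved redox split of a pooled master component (fractions of total).
redox_split <- function(result, master = "Fe3") {
  tot <- result$totals[[master]]
  has_e <- "e" %in% colnames(result$A)
  sel <- result$A[, master] > 0
  red <- if (has_e) sel & result$A[, "e"] > 0 else sel & FALSE
  solid <- if (!is.null(result$solids))
    sum(result$solids$amount[result$solids$active]) else 0
  c(reduced = sum(result$species$concentration[red] *
                    result$A[red, master]) / tot,
    oxidized = sum(result$species$concentration[sel & !red] *
                     result$A[sel & !red, master]) / tot,
    solid = solid / tot)
}

.base_totals <- function(I) c(Na = I, Cl = I)

#' Zn complexation versus pH at different ionic strengths
#'
#' Single-ligand (and optionally mixed-ligand) Zn speciation over the pH
#' grid at each ionic strength, reporting the fraction of Zn complexed per
#' ligand.
#'
#' @param db an `equilibrium_database`.
#' @param config a [scenario_config()]; fields used: `I_set` (default
#'   0.02/0.1/0.7), `pH_grid`, `ligands` (default `"Pdma"`; add `"Dma"`
#'   for the natural-phytosiderophore comparison), `mixed` (logical).
#' @return a `scenario_report`.
#' @export
run_ionic_strength <- function(db,
                               config = scenario_config(
                                 "ionic_strength",
                                 I_set = c(0.02, 0.1, 0.7),
                                 ligands = "Pdma", mixed = FALSE)) {
  ligands <- config$ligands %||% "Pdma"
  for (lg in ligands) .check_ligand(db, lg)
  runs <- if (isTRUE(config$mixed) && length(ligands) > 1)
    list(ligands) else as.list(ligands)
  rows <- list()
  for (I in config$I_set) {
    for (lgset in runs) {
      totals <- c(Zn = config$metal_total,
                  stats::setNames(rep(config$ligand_total, length(lgset)),
                                  lgset),
                  .base_totals(I))
      spec <- solution_spec(totals, pH = config$pH_grid[1], I = I)
      tab <- sweep_axis(db, spec, "pH", config$pH_grid)
      res <- attr(tab, "results")
      for (i in seq_along(res)) for (lg in lgset)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = "ionic_strength", pH = config$pH_grid[i],
          Eh_mV = NA_real_, I = I, metal = "Zn", ligand = lg,
          ratio = NA_real_, quantity = "fraction",
          value = fraction_complexed(res[[i]], "Zn", lg),
          mixed = length(lgset) > 1, stringsAsFactors = FALSE)
    }
  }
  .report(config, rows)
}

#' Redox-dependent Cu and Fe complexation with PDMA
#'
#' One metal at a time (1e-6 mol/dm^3 with PDMA 1e-5) under fixed Eh, with
#' the Cu(II)/Cu(I) and Fe(III)/Fe(II) couples active and ferric oxide
#' precipitation allowed; reports the complexed fraction and the
#' dissolved redox split per grid point.
#'
#' @param db an `equilibrium_database`.
#' @param config fields used: `Eh_set` (default -300/+350), `I_set`,
#'   `pH_grid`, `metals` (masters; default `c("Cu", "Fe3")`).
#' @return a `scenario_report`.
#' @export
run_redox <- function(db,
                      config = scenario_config("redox",
                                               I_set = c(0.02, 0.1, 0.7),
                                               metals = c("Cu", "Fe3"))) {
  metals <- config$metals %||% c("Cu", "Fe3")
  rows <- list()
  for (m in metals) for (Eh in config$Eh_set) for (I in config$I_set) {
    totals <- c(stats::setNames(config$metal_total, m),
                Pdma = config$ligand_total, .base_totals(I))
    spec <- solution_spec(totals, pH = config$pH_grid[1],
                          pe = eh_to_pe(Eh), I = I, allow_solids = TRUE)
    tab <- sweep_axis(db, spec, "pH", config$pH_grid)
    res <- attr(tab, "results")
    for (i in seq_along(res)) {
      r <- res[[i]]
      sp <- redox_split(r, m)
      add <- function(q, v) rows[[length(rows) + 1L]] <<- data.frame(
        scenario = "redox", pH = config$pH_grid[i], Eh_mV = Eh, I = I,
        metal = m, ligand = "Pdma", ratio = NA_real_, quantity = q,
        value = v, mixed = FALSE, stringsAsFactors = FALSE)
      add("fraction", fraction_complexed(r, m, "Pdma"))
      add("fraction_reduced", sp[["reduced"]])
      add("fraction_oxidized", sp[["oxidized"]])
      add("fraction_solid", sp[["solid"]])
      add("complex_reduced", complex_conc(r, m, "Pdma", reduced = TRUE) /
            r$totals[[m]])
      add("complex_oxidized", complex_conc(r, m, "Pdma", reduced = FALSE) /
            r$totals[[m]])
    }
  }
  .report(config, rows)
}

#' Eight-metal competition for PDMA
#'
#' All metals studied (Zn, Fe, Ni, Cu, Mg, Mn, Co; iron and copper pooled
#' over their redox states) at 1e-6 mol/dm^3 each with PDMA 1e-5, under
#' fixed Eh; reports per-metal complexed fractions and the log selectivity
#' ratio versus Zn.
#'
#' @param db an `equilibrium_database`.
#' @param config fields used: `Eh_set`, `I_set` (scalar, default 0.1),
#'   `pH_grid`.
#' @return a `scenario_report`.
#' @export
run_metal_competition <- function(db,
                                  config = scenario_config(
                                    "metal_competition")) {
  masters <- c("Zn", "Fe3", "Cu", "Ni", "Co", "Mn", "Mg")
  rows <- list()
  for (Eh in config$Eh_set) for (I in config$I_set) {
    totals <- c(stats::setNames(rep(config$metal_total, length(masters)),
                                masters),
                Pdma = config$ligand_total, .base_totals(I))
    spec <- solution_spec(totals, pH = config$pH_grid[1],
                          pe = eh_to_pe(Eh), I = I, allow_solids = TRUE)
    tab <- sweep_axis(db, spec, "pH", config$pH_grid)
    res <- attr(tab, "results")
    for (i in seq_along(res)) {
      r <- res[[i]]
      for (m in masters) {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = "metal_competition", pH = config$pH_grid[i],
          Eh_mV = Eh, I = I, metal = m, ligand = "Pdma", ratio = NA_real_,
          quantity = "fraction", value = fraction_complexed(r, m, "Pdma"),
          mixed = FALSE, stringsAsFactors = FALSE)
        if (m != "Zn")
          rows[[length(rows) + 1L]] <- data.frame(
            scenario = "metal_competition", pH = config$pH_grid[i],
            Eh_mV = Eh, I = I, metal = m, ligand = "Pdma",
            ratio = NA_real_, quantity = "logS",
            value = as.numeric(selectivity_log_S(r, m)), mixed = FALSE,
            stringsAsFactors = FALSE)
      }
      ## redox-resolved complex fractions for iron and copper
      for (m in c("Fe3", "Cu")) for (red in c(TRUE, FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = "metal_competition", pH = config$pH_grid[i],
          Eh_mV = Eh, I = I, metal = m, ligand = "Pdma", ratio = NA_real_,
          quantity = if (red) "complex_reduced" else "complex_oxidized",
          value = complex_conc(r, m, "Pdma", reduced = red) /
            r$totals[[m]],
          mixed = FALSE, stringsAsFactors = FALSE)
    }
  }
  .report(config, rows)
}

#' Zn partition between PDMA and a competing organic ligand
#'
#' Single-ligand runs for PDMA and the competitor, plus the mixed run at
#' molar ratio Zn : PDMA : competitor = 1 : 10 : 10.
#'
#' @param db an `equilibrium_database`.
#' @param config fields used: `competitor` (one of `"Cit"`, `"Mal"`,
#'   `"Oxa"`, `"Dfob"`, `"Dma"`), `I_set`, `pH_grid`,
#'   `competitor_total` (default `ligand_total`).
#' @return a `scenario_report`.
#' @export
run_ligand_competition <- function(db,
                                   config = scenario_config(
                                     "ligand_competition",
                                     I_set = c(0.02, 0.1, 0.7),
                                     competitor = "Cit")) {
  comp <- config$competitor %||% "Cit"
  avail <- c("Cit", "Mal", "Oxa", "Dfob", "Dma")
  if (!comp %in% avail)
    stop("unknown competitor '", comp, "'; available: ",
         paste(avail, collapse = ", "))
  .check_ligand(db, comp)
  comp_total <- config$competitor_total %||% config$ligand_total
  rows <- list()
  for (I in config$I_set) {
    runsets <- list(single_pdma = c(Pdma = config$ligand_total),
                    single_comp = stats::setNames(comp_total, comp))
    if (comp_total > 0)
      runsets$mixed <- c(Pdma = config$ligand_total,
                         stats::setNames(comp_total, comp))
    else runsets$mixed <- runsets$single_pdma
    for (rn in names(runsets)) {
      totals <- c(Zn = config$metal_total, runsets[[rn]], .base_totals(I))
      totals <- totals[totals > 0 | names(totals) == "H"]
      spec <- solution_spec(totals, pH = config$pH_grid[1], I = I)
      tab <- sweep_axis(db, spec, "pH", config$pH_grid)
      res <- attr(tab, "results")
      for (i in seq_along(res)) for (lg in names(runsets[[rn]]))
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = "ligand_competition", pH = config$pH_grid[i],
          Eh_mV = NA_real_, I = I, metal = "Zn", ligand = lg,
          ratio = NA_real_, quantity = paste0("fraction_", rn),
          value = fraction_complexed(res[[i]], "Zn", lg),
          mixed = rn == "mixed", stringsAsFactors = FALSE)
    }
  }
  .report(config, rows)
}

#' PDMA speciation in the pot-trial nutrient solution
#'
#' Speciates the nutrient-solution composition (see
#' [suzuki_nutrient_solution()]) with PDMA added at a ligand-limited
#' fertilizer dose under reducing and oxidizing conditions, and reports how
#' the \[M(PDMA)\] complex pool partitions among the metals (plus log S
#' versus Zn and the bound/free ligand split).
#'
#' @param db an `equilibrium_database` (must carry EDTA constants).
#' @param config fields used: `Eh_set`, `pH_grid` (default 3-10),
#'   `pdma_total` (default 2.5e-7, sub-stoichiometric to the Zn pool),
#'   `jitter`, `seed`.
#' @return a `scenario_report`.
#' @export
run_soil_solution <- function(db,
                              config = scenario_config(
                                "soil_solution",
                                pH_grid = seq(3, 10, by = 0.25),
                                pdma_total = 2.5e-7)) {
  if (!"Edta" %in% db$components$name ||
      !any(vapply(db$species$stoich, function(s) "Edta" %in% names(s),
                  logical(1))))
    stop("EDTA constants missing from the database; the nutrient solution ",
         "cannot be speciated without them")
  base <- suzuki_nutrient_solution(config$pdma_total %||% 2.5e-7,
                                   jitter_fraction = config$jitter %||% 0,
                                   seed = config$seed %||% 1L)
  masters <- c("Zn", "Fe3", "Cu", "Mn", "Mg")
  rows <- list()
  I <- config$I_set[1]
  for (Eh in config$Eh_set) {
    totals <- c(base, .base_totals(I))
    totals <- totals[totals > 0]
    spec <- solution_spec(totals, pH = config$pH_grid[1],
                          pe = eh_to_pe(Eh), I = I, allow_solids = TRUE)
    tab <- sweep_axis(db, spec, "pH", config$pH_grid)
    res <- attr(tab, "results")
    for (i in seq_along(res)) {
      r <- res[[i]]
      pool <- vapply(masters, function(m)
        complex_conc(r, m, "Pdma", one_to_one = TRUE), numeric(1))
      pool_red <- complex_conc(r, "Fe3", "Pdma", reduced = TRUE,
                               one_to_one = TRUE)
      all_bound <- sum(vapply(masters, function(m)
        complex_conc(r, m, "Pdma"), numeric(1)))
      tot_pool <- sum(pool)
      add <- function(m, q, v) rows[[length(rows) + 1L]] <<- data.frame(
        scenario = "soil_solution", pH = config$pH_grid[i], Eh_mV = Eh,
        I = I, metal = m, ligand = "Pdma", ratio = NA_real_, quantity = q,
        value = v, mixed = FALSE, stringsAsFactors = FALSE)
      for (m in masters)
        add(m, "pdma_share",
            if (tot_pool > 0) pool[[m]] / tot_pool else 0)
      add("Fe3", "pdma_share_ferrous",
          if (tot_pool > 0) pool_red / tot_pool else 0)
      for (m in setdiff(masters, "Zn"))
        add(m, "logS", as.numeric(selectivity_log_S(r, m)))
      lig_tot <- r$totals[["Pdma"]]
      add("free", "fraction_uncomplexed", 1 - all_bound / lig_tot)
    }
  }
  .report(config, rows)
}

#' Excess-metal tolerance grids for the Zn-PDMA complex
#'
#' Part (a): excess Cu(II) or Fe(III) over the Zn-PDMA system (the
#' competitor at `ratio` times the PDMA dose, zinc at trace level); the
#' percent reduction of the Zn-PDMA complex relative to the identical
#' solution without the competitor.  Part (b): excess Zn over the
#' competitor; the percent of the PDMA pool converted to Zn-PDMA.  PDMA
#' is present at 1e-6 mol/dm^3, in excess of the trace zinc.
#'
#' @param db an `equilibrium_database`.
#' @param config fields used: `part` ("a", "b" or "both"), `ratios_a`
#'   (competitor excess, default 2/5/10/20/50), `ratios_b` (Zn/competitor,
#'   default 2/5/10), `pH_set` (default 5/7/9), `Eh_set`,
#'   `zn_total` (part a trace zinc, default 1e-8),
#'   `competitor_total` (part b, default 1e-6), `pdma_total` (default
#'   1e-6).
#' @return a `scenario_report`.
#' @export
run_excess_grid <- function(db,
                            config = scenario_config(
                              "excess_grid", part = "both",
                              ratios_a = c(2, 5, 10, 20, 50),
                              ratios_b = c(2, 5, 10),
                              pH_set = c(5, 7, 9))) {
  part <- config$part %||% "both"
  ratios_a <- config$ratios_a %||% c(2, 5, 10, 20, 50)
  ratios_b <- config$ratios_b %||% c(2, 5, 10)
  pH_set <- config$pH_set %||% c(5, 7, 9)
  comp_tot <- config$competitor_total %||% 1e-6
  pdma <- config$pdma_total %||% 1e-6
  I <- config$I_set[1]
  if (any(c(ratios_a, ratios_b) <= 0)) stop("ratios must be positive")
  znl <- function(totals, Eh, pH) {
    spec <- solution_spec(c(totals, .base_totals(I)), pH = pH,
                          pe = eh_to_pe(Eh), I = I, allow_solids = TRUE)
    complex_conc(solve_equilibrium(db, spec), "Zn", "Pdma")
  }
  rows <- list()
  zn_trace <- config$zn_total %||% 1e-8
  if (part %in% c("a", "both")) {
    for (comp in c("Cu", "Fe3")) for (Eh in config$Eh_set)
      for (pH in pH_set) for (rr in ratios_a) {
        with_c <- znl(c(Zn = zn_trace,
                        stats::setNames(rr * pdma, comp), Pdma = pdma),
                      Eh, pH)
        without <- znl(c(Zn = zn_trace, Pdma = pdma), Eh, pH)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = "excess_grid", pH = pH, Eh_mV = Eh, I = I,
          metal = comp, ligand = "Pdma", ratio = rr,
          quantity = "percent_reduction",
          value = if (without > 0) 100 * (1 - with_c / without) else 0,
          mixed = FALSE, stringsAsFactors = FALSE)
      }
  }
  if (part %in% c("b", "both")) {
    for (comp in c("Cu", "Fe3")) for (Eh in config$Eh_set)
      for (pH in pH_set) for (rr in ratios_b) {
        zn_tot <- comp_tot * rr
        with_c <- znl(c(Zn = zn_tot,
                        stats::setNames(comp_tot, comp), Pdma = pdma),
                      Eh, pH)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = "excess_grid", pH = pH, Eh_mV = Eh, I = I,
          metal = comp, ligand = "Pdma", ratio = rr,
          quantity = "percent_formation", value = 100 * with_c / pdma,
          mixed = FALSE, stringsAsFactors = FALSE)
      }
  }
  .report(config, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
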