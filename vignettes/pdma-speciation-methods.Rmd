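---
title: "Modeling metal-PDMA speciation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling metal-PDMA speciation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmaspec)
```

Proline-2'-deoxymugineic acid (PDMA) is a synthetic analogue of the rice
phytosiderophore DMA, of interest as a zinc fertilizer for alkaline and
flooded paddy soils. Whether a PDMA dose actually delivers zinc depends on
aqueous chemistry: the ligand's protonation state, the competition between
Zn(II) and the other cations of the soil solution (Cu, Fe, Ni, Co, Mn, Mg),
the redox state of iron and copper, the ionic strength of the medium, and
precipitation of ferric oxides. `pdmaspec` implements the full computational
chain for these questions: a chemical-equilibrium solver, a potentiometric
titration simulator and refinement engine, a constants database for the
PDMA system, and scripted computational experiments (`analysis/`).

## The equilibrium model

A solution is described by component totals $T_i$ (mol/dm$^3$). Every
dissolved species $S_j$ is a product of components with cumulative
formation constant $\beta_j$:

$$[S_j] = \beta_j \prod_i c_i^{a_{ji}},$$

where $c_i$ are free component concentrations and $a_{ji}$ the
stoichiometric coefficients (hydroxo species carry $a_{j,H} = -1$, encoding
$\mathrm{H_2O - H^+}$; water activity is taken as unity). The solver finds
$\log c_i$ such that $\sum_j a_{ji}[S_j] = T_i$ for every non-fixed
component, by damped Newton iteration with an analytic Jacobian, preceded
by component-wise logarithmic correction steps that bring strongly
hydrolysed cations (Fe$^{3+}$) into the Newton basin. Convergence requires
relative mass-balance residuals below $10^{-10}$ (tests assert
$10^{-8}$). Warm starts propagate along sweeps; a failed warm start is
retried cold.

pH and pe are fixed-activity components: they are excluded from mass
balance, the convention of geochemical speciation programs for pH/Eh
sweeps. For scenario work pH is an activity ($-\log_{10} a_{H^+}$,
converted to a concentration with the Davies activity coefficient); the
titration module uses the concentration scale, which is what a calibrated
glass electrode measures. Redox is handled with an electron component of
activity $10^{-\mathrm{pe}}$; Eh in mV converts as
$\mathrm{pe} = E_h F / (\ln 10\, R T)$. Ferrous iron and Cu(I) are
independent components when pe is not fixed (a titration of an Fe(II) salt
does not equilibrate with Fe(III)); when pe is fixed they are pooled onto
the oxidized master via the couples Fe$^{3+}$/Fe$^{2+}$
($\log K = 13.032$) and Cu$^{2+}$/Cu$^{+}$ ($\log K = 2.72$).

Activity corrections use the Davies equation,
$\log\gamma = -A z^2 (\sqrt{I}/(1+\sqrt{I}) - b I)$ with $A = 0.51$ at
298.1 K. The linear coefficient is the canonical $b = 0.3$; the model
warns above $I = 0.5$ mol/dm$^3$ (the 0.7 mol/dm$^3$ scenario relies on an
extrapolation, as any Davies-based treatment must). All constants are
stored with their measurement ionic strength and converted to intrinsic
($I = 0$) values at load time via
$\log\beta_0 = \log\beta_c - A f(I)\,\Delta z^2$,
$\Delta z^2 = z_{sp}^2 - \sum_i a_{ji} z_i^2$, then re-conditioned to the
working ionic strength of each solve. Ionic strength is fixed at the
background-electrolyte value by default (`self_consistent` mode is
available but off, since the trace totals contribute negligibly).

Only one solid is included by default: ferrihydrite-type Fe(OH)$_3$
($\log K_{sp}$ convention $\mathrm{Fe(OH)_3 + 3H^+ = Fe^{3+} + 3H_2O}$,
$\log K = 4.891$), as a proxy for the ferric oxides that form under
oxidizing conditions. At fixed pH an active solid pins the free Fe$^{3+}$
concentration; the solver activates/deactivates it by saturation index
with the solid retained at zero mass exactly at saturation, keeping sweeps
continuous.

## The constants database

`pdma_database()` embeds the potentiometrically determined constants of
the PDMA system (0.15 mol/dm$^3$ NaCl, 298.1 K): three ligand protonation
steps (log $K_a$ 10.32, 8.08, 2.66; the two low-pH steps 2.47 and 2.01
from an earlier determination are shipped as optional rows, on by default,
because the potentiometric window cannot resolve them) and the ML / MHL /
ML(OH) complexes of Zn, Fe(II), Fe(III), Cu, Co, Ni, Mg and Mn. Stepwise
constants combine log-additively to cumulative $\beta$ on the (M, L, H)
basis. The divalent ML series follows the Irving-Williams ordering, which
the test suite asserts directly on the shipped file. Two reported
inconsistencies are preserved as printed and flagged in the notes column:
the Cu value (17.29 in the table vs 15.69 in one text passage) and the
unusually large Mg MHL step (9.26, exceeding its ML value).

Auxiliary constants (water, metal hydrolysis, chloro and sulfate ion
pairs, redox couples, competing ligands, EDTA, ferrihydrite) come from
standard compilations of the minteq/NIST lineage and are tagged
`auxiliary:*`. Three of these choices are load-bearing and deliberate:

* **Chloro complexes of Cu(II) and Zn.** The strong fall of Cu-PDMA
  complexation between $I$ = 0.02 and 0.7 mol/dm$^3$ NaCl cannot come from
  the Davies correction alone (the effective exchange reaction has a small
  $\Delta z^2$); chloride complexation of the free metal supplies most of
  the high-salt suppression. Cu(I) is modeled with its strong dichloro and
  trichloro complexes, which is why reducing saline solutions keep copper
  out of the ligand pool.
* **Zn hydrolysis.** The NIST-critical values (ZnOH$^+$ $-8.997$,
  Zn(OH)$_2$ $-17.794$, Zn(OH)$_3^-$ $-28.091$) are used rather than the
  older Baes-Mesmer $\beta_2 = -16.9$; the choice matters only above
  pH $\approx$ 9.5, where it sets how much free Zn$^{2+}$ survives to hold
  the ligand against Mg and Mn.
* **EDTA as an iron carrier.** The nutrient solution supplies iron as
  Fe(III)-EDTA. EDTA is modeled with its protonation and its Fe(III) and
  Fe(II) complexes only. Including the full trace-metal EDTA set with
  equimolar Fe:EDTA would let EDTA strip Zn entirely (ZnEDTA
  $\log K \approx 16.4$ against FeII-EDTA 14.3), which contradicts the
  ligand-partition behaviour this scenario is built to reproduce; treating
  the chelate as iron-specific is an explicit, documented approximation.

The database ships as `inst/extdata/pdma_constants.csv` (stoichiometry,
charge, published stepwise value verbatim, cumulative value on its native
scale, computed intrinsic value, provenance). Loading re-validates charge
balance, component references, and the recorded intrinsic values.

## Titration simulation and refinement

The simulated experiment follows the bench protocol: 30 mL of PDMA
(6.7$\times 10^{-4}$ mol/dm$^3$) with metal (6.0$\times 10^{-4}$, ligand
slightly in excess to suppress hydrolysis), 0.15 mol/dm$^3$ NaCl, titrated
with 0.1 mol/dm$^3$ NaOH over pH 3-10 in 80-100 points. The initial
strong-acid excess is solved so the untitrated solution sits at pH 2.8
(about 3.4$\times 10^{-3}$ mol/dm$^3$ for the ligand-only system). Each
point dilution-corrects the totals and solves the equilibrium; emf
readings are $E^0 + s\,\log_{10}[\mathrm{H^+}]$ with a Nernstian default
slope. Electrode calibration fits $E^0$ and $s$ on strong acid/base
curves away from equivalence, where $[\mathrm{H^+}]$ is analytic.

`refine_constants()` minimises the weighted squared reading residuals
jointly over all replicate curves (Levenberg-Marquardt via `minpack.lm`),
refining the conditional cumulative constants of a chosen species set
while everything else stays fixed. Weights follow the standard
potentiometric error model
$w_i = 1/(\sigma_E^2 + (dE/dV)_i^2 \sigma_v^2)$ with defaults
$\sigma_E = 0.1$ mV (or 0.003 pH) and $\sigma_v = 0.002$ mL — the paper
trail for these magnitudes is conventional practice, not a measured
value, and both are configurable. Reported uncertainties are 1$\sigma$
standard deviations from the Gauss-Newton covariance at the optimum.
Species that never reach 1% of any of their components across the curves
are flagged ill-conditioned and excluded rather than silently returned.
The intended workflow refines protonation constants from metal-free
curves first, then holds them fixed for the metal refinements
(`analysis/01_refine_constants.R`).

Noise generation (`make_titration_dataset`) perturbs the *delivered*
volume before the equilibrium is evaluated — the physical error source —
and records the nominal volume, then adds reading noise; all generators
are pure functions of their inputs and seed.

## Scenario design choices

The scripted experiments use the standard working concentrations
([M] $10^{-6}$, [L] $10^{-5}$ mol/dm$^3$) on pH 3-9 grids, $I \in$
{0.02, 0.1, 0.7}, Eh $\in$ {$-300$, $+350$} mV. Points the design left
genuinely open, and how they were closed:

* **Selectivity readout.** $\log S$ compares the concentrations of the
  1:1 [M(PDMA)] complexes (option `complexes = "all"` sums the protonated
  and hydroxo forms too). The one-to-one definition is the quantity the
  published selectivity plateaus track; including NiHL would raise the
  acidic Ni readout by ~0.8 log units.
* **Nutrient-solution PDMA dose.** The pot-trial scenario uses
  2.5$\times 10^{-7}$ mol/dm$^3$ PDMA — sub-stoichiometric to the
  0.5 µM Zn pool. Ligand-limited conditions are the regime in which the
  dissolved dose operates (free PDMA in soil is scavenged and diluted),
  and they are the only regime in which the complexed-ligand pool can sit
  quantitatively on Zn: any ligand excess is taken up by 0.5 mM Mg and by
  Mn at alkaline pH. The reported `pdma_share` quantities partition the
  [M(PDMA)] pool among the metals.
* **Excess grids.** The competitor ("excess Cu/Fe") is dosed at 2-50
  times the PDMA concentration with zinc at trace level ($10^{-8}$
  mol/dm$^3$); the percent reduction is taken against the identical
  solution with the competitor removed, and part (b) reports Zn-PDMA as a
  percentage of the ligand pool. A competitor at or below the ligand dose
  cannot exhaust the free-ligand buffer, so the tolerance behaviour the
  grids probe only exists with the competitor in excess of the dose.

## What the synthetic data do and do not show

The titration generator reproduces the protocol structure (dilution,
replicates, reading/burette noise, acid excess) but not electrode drift,
junction potentials, carbonate contamination, or slow equilibration —
passing recovery tests therefore demonstrates the estimator's
correctness and precision under the stated error model, not robustness
to systematic bench artifacts. The nutrient-solution generator jitters
the salt recipe (Fe and EDTA together, as the compound they are) and
says nothing about real soil-solution matrices: sorption, organic
matter, carbonate and microbial turnover are outside the model, which
covers solution processes only. The shipped DMA constants are synthetic
placeholders for qualitative ligand comparison and are labelled as such
in the database.

## Known limitations

* The Davies model is used to 0.7 mol/dm$^3$, past its validity range;
  no Pitzer/SIT option exists, and no temperature corrections are made.
* Under the equimolar Fe:EDTA treatment the model does not release
  Fe(III) to PDMA at alkaline pH, so the oxidizing-side decline of Zn
  complexation above pH 8 reported for the nutrient solution is not
  reproduced; the reducing-side partition, which drives the fertilizer
  recommendation, is.
* Two cells of the excess-metal grids (reducing pH 5 "99% reduction",
  and the ratio-dependent oxidizing Fe cells at pH 7) cannot be obtained
  from the shipped constants under any concentration assignment we
  found: Cu(I) is inert and dissolved Fe(III) is pinned by ferrihydrite,
  so the competitor total cannot matter there.
* Solids precipitate only at fixed pH (each solid pins one component);
  titrations are solved without solids.

Problem sizes used throughout (90-point titrations, 0.1-0.25 pH grids,
25-draw robustness batches) were chosen as the smallest grids on which
the reported quantities are stable to well below their tolerances.
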