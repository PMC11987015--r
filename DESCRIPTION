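Package: pdmaspec
Title: Metal-Ligand Speciation Modeling and Stability-Constant Refinement for
    the Synthetic Phytosiderophore PDMA
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemical equilibrium speciation of metal complexes of the
    synthetic phytosiderophore proline-2'-deoxymugineic acid (PDMA) in soil
    solutions, and refinement of proton and metal stability constants from
    potentiometric titration curves. Implements a damped-Newton mass-balance
    speciation solver with Davies activity corrections and pe/Eh redox
    coupling, a titration simulator and Levenberg-Marquardt constant
    refinement engine, a thermodynamic constants database for the PDMA
    system, and scripted computational experiments (ionic strength, redox,
    metal and ligand competition, nutrient-solution speciation, excess-metal
    tolerance grids).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
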