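Package: reesfel
Title: Protein-Ligand Free-Energy Landscapes from Red-Edge Excitation
    Shift Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical-mechanical modelling of the red-edge excitation
    shift (REES) of a charge-transfer fluorophore distributed over a
    finite set of discrete protein-ligand microstates.  Marcus free-energy
    surfaces describe absorption and emission within each microstate;
    Boltzmann weighting over a parametric ground-state free-energy
    landscape A*i^b yields theoretical REES curves.  The package fits
    Boltzmann sigmoids to observed excitation/emission data, fits the
    landscape model to the sigmoid representation by least squares with
    AIC-based model comparison, and derives microstate energetics:
    inter-state gaps, Marcus activation barriers, and a decomposition of
    ligand binding free energy into surface association and intrusion
    terms.  Includes a synthetic-data generator and a parameter-recovery
    benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
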