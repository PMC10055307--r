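Package: coopkin
Title: Thermodynamic Linkage Analysis for Double-Drugging of Kinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of cooperativity between orthosteric and
    allosteric kinase modulators ("double-drugging") under a
    conformational-selection thermodynamic linkage model. Provides the
    two-state (and nested multi-state) ensemble model with apparent
    affinities, equilibrium shifts, cooperativity factors and their inverse
    problems; forward simulation and fitting of isothermal titration
    calorimetry experiments (direct and competitive-replacement);
    tight-binding (Morrison) fluorescence titration fitting with a
    step-function diagnostic; four-parameter dose-response fitting,
    dose-for-residual-activity extraction with jackknife errors, and
    model-predicted synergy grids; plus seedable synthetic-data generators
    and a parameter-recovery harness for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
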