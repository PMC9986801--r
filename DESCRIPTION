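Package: itermodel
Title: Iterative Real-Space Model Building Toolkit for Crystallographic Maps
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the bespoke real-space stages of iterative
    prediction-based crystallographic model building: processing of
    predicted models by per-residue confidence (pLDDT trimming, conversion
    of confidence scores to atomic displacement parameters, domain
    splitting), model-derived density maps and per-residue or global
    map-model correlation with mask-radius and side-chain-B optimization,
    a three-step map-driven model trimming algorithm, anchor-based
    superpose-and-morph deformation of predicted models onto working
    models, symmetry-aware model comparison metrics (Kabsch superposition,
    Calpha r.m.s.d., completeness, coverage), and a convergence-controlled
    cycle orchestrator with pluggable engines plus deterministic mock
    engines and a synthetic-fixture generator. Atomic models are read and
    written as PDB or mmCIF; density maps as CCP4/MRC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
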