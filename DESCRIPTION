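Package: emuflux
Title: Steady-State 13C Metabolic Flux Analysis via Elementary Metabolite Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for steady-state 13C metabolic flux analysis (13C-MFA) of
    bacterial central metabolism. Parses carbon-mapped metabolic network models,
    corrects raw GC-MS intensity data of derivatized amino-acid fragments for
    natural isotope abundance, tracer impurity and inoculum dilution, simulates
    mass isotopomer distributions (MIDs) through the network with the elementary
    metabolite unit (EMU) decomposition, and estimates intracellular fluxes by
    multi-start weighted nonlinear least squares. Fit quality is assessed by a
    chi-squared test and flux uncertainty by Monte-Carlo bootstrap confidence
    intervals. A full-isotopomer brute-force simulator is included as an
    independent cross-check, together with carbon-fate and ATP/cofactor
    accounting (maintenance energy, P/O-ratio sensitivity) and a synthetic
    labeling-experiment generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
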