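Package: itcbridge
Title: Binding Thermodynamics and Speciation of LC8-Bridged 53BP1 Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward and inverse models for isothermal titration calorimetry
    (ITC) of the dynein light chain LC8 binding to trimeric 53BP1 constructs:
    the one-set-of-sites (Wiseman) isotherm, a constrained three-event
    sequential-binding-sites model of an LC8-bridged hexamer, inverse-variance
    aggregation of replicate fits, composition-to-mass bookkeeping for trimer
    and dimer-of-trimers complexes, and a mass-action speciation model of
    LC8-bridged 53BP1 oligomers.  Includes a seeded synthetic-isotherm
    generator so every stage is testable without instrument files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
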