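Package: allomod
Title: Allosteric Modulator Pharmacology and Structure-Based Screen Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of G protein-coupled receptor allosteric
    pharmacology and evaluation of structure-based virtual screens for
    allosteric modulators. Fits radioligand interaction-binding data to the
    allosteric ternary complex model and cAMP concentration-response data to
    the operational model of allosterism by global nonlinear least squares,
    derives modulator affinity (pKB), binding cooperativity (log alpha) and
    functional cooperativity (log alphabeta), and calls screening hits from
    replicate shifts in orthosteric agonist affinity and potency. Implements
    early-enrichment metrics for docking screens (ROC, adjusted logAUC over
    ensembles of MD snapshots), property-matched decoy selection, and the
    screening funnel: rank cuts, hydrogen-bond pose filtering, Tanimoto
    leader clustering and analog searches. Includes seeded generators for
    synthetic assay and docking data so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    lhs,
    jsonlite,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
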