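Package: combosens
Title: Drug Combination Sensitivity and Synergy Scoring from Cross and
    Full-Matrix Dose-Response Designs
Version: 0.1.0
Authors@R:
    person("combosens", "developers", email = "combosens@example.org",
           role = c("aut", "cre"))
Description: Scores drug-combination screens run either as a full
    factorial dose matrix or as a cost-effective cross design in which
    each drug is titrated against the partner fixed at its IC50. Fits
    monotherapy logistic and combination four-parameter log-logistic
    dose-response curves, computes closed-form log10-scale AUCs, derives
    the combination sensitivity score (CSS) with its replicate-style
    consistency QC, and the S synergy scores referenced against
    monotherapy AUCs. Full-matrix reference synergy models (HSA, Bliss,
    Loewe, ZIP) define a consensus synergy/antagonism ground truth with
    ROC / precision-recall evaluation and an S-S (sensitivity-synergy)
    prioritization rule. Includes a synthetic dose-response simulator
    with injectable interaction effects, a drug-combination feature
    builder (bitwise OR of binary target/fingerprint profiles) with a
    cross-validated prediction harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
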