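Package: sinswitch
Title: Growth-Rate-Coupled Modelling of the SinI-SinR-SlrR Biofilm Switch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-scale simulation of Bacillus subtilis biofilm-matrix
    cell-fate decisions. A Moser-type batch-growth model drives the
    population growth rate; growth rate sets phosphorylated Spo0A and,
    via replication timing, gene dosage; both feed a bistable
    SinI-SinR-SlrR regulatory switch simulated deterministically
    (steady states, bifurcation and hysteresis scans) and stochastically
    (next-reaction lineage simulation with explicit gene replication and
    binomial partitioning at division). Includes single-cell fate
    classification (matrix-on versus sporulating), population summaries,
    and a synthetic dual-reporter microscopy pipeline with background
    thresholding, per-image fractions and two-sample comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
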