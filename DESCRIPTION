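Package: hyradsim
Title: Simulation and Analysis of Hybridization Capture with RAD-Derived Probes
Version: 0.1.0
Authors@R:
    person("hyradsim", "developers", email = "hyradsim@example.org",
           role = c("aut", "cre"))
Description: An in-silico implementation of the hyRAD protocol for
    reduced-representation sequencing of degraded (museum) DNA. Simulates
    double-digest RAD probe generation (restriction digestion and size
    selection), diploid population cohorts with a complete variant truth
    table, shotgun libraries with post-mortem cytosine deamination damage
    and contaminant spike-ins, and in-solution hybridization capture with
    configurable signal-to-noise. Implements the downstream pipeline
    natively: locus catalog construction by greedy identity clustering,
    read-based contig extension and de-novo assembly, seed-and-extend read
    mapping with uniqueness classes, PCR duplicate removal, damage profile
    estimation and base quality rescaling, diploid genotype-likelihood SNP
    calling, a quality/allele-count/presence/depth/paralog filter cascade,
    and population-structure and restriction-site dropout summaries. All
    components are verifiable against planted ground truth on synthetic
    genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    stringi,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
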