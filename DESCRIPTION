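Package: craswitch
Title: Agent-Based Simulation of the E. coli Cra Glycolysis-Gluconeogenesis Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell-resolved simulation of Escherichia coli populations
    growing in a chemostat that alternates between glucose and acetate. Each
    cell carries a four-reaction metabolic model coupled to the Cra regulatory
    circuit (fructose-1,6-bisphosphate represses Cra; active Cra induces the
    acetate uptake enzyme), stochastic bursty protein expression with tunable
    noise, binomial protein partitioning at division, and random washout.
    Includes the deterministic bistability analysis of the circuit and the
    evolutionary experiment designs built on the simulator: competitive
    fitness assays, population bottleneck and lag statistics, fitness
    landscapes over Cra-fbp dissociation constants, allele competitions, and
    fixation of beneficial alleles from a single mutant.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
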