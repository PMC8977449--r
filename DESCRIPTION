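Package: painnma
Title: Bayesian Network Meta-Analysis of Drug Therapies for Neuropathic
    Pain After Spinal Cord Injury
Version: 0.1.0
Authors@R:
    person("painnma", "developers", email = "painnma@example.org",
           role = c("aut", "cre"))
Description: Tools for arm-level network meta-analysis of randomized
    controlled trials, built around the drug-therapy evidence base for
    neuropathic pain after spinal cord injury. Provides an arm-level trial
    data model with validation and network-composition summaries,
    standardized mean difference (Hedges' g) and odds-ratio effect sizes,
    DerSimonian-Laird pairwise pooling and comparison-adjusted funnel
    diagnostics, a Bayesian random-effects consistency model fitted by a
    purpose-built Gibbs/Metropolis sampler with DIC and convergence
    diagnostics, node-splitting assessment of inconsistency, SUCRA-based
    treatment ranking with multi-outcome heat-map aggregation, a synthetic
    trial-network generator with known ground truth, and a command-line
    interface. Ships an arm-level transcription of a 20-trial, 12-node
    network (11 drugs plus placebo).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
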