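Package: adcausal
Title: Causal Structure Discovery Benchmarks on the Alzheimer's Biomarker Cascade
Version: 0.1.0
Authors@R: person("ADNI Causal Benchmark", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Benchmarks constraint-based (FCI-style), score-based (greedy
    equivalence search with Gaussian BIC) and structural-equation-model
    stepwise edge search against a literature-derived gold-standard causal
    graph of the Alzheimer's disease biomarker cascade (amyloid-beta,
    phosphorylated tau, FDG-PET metabolism, diagnosis, and demographic risk
    factors). Includes a calibrated linear-Gaussian cohort simulator for
    cross-sectional and two-visit longitudinal designs, tiered background
    knowledge, bootstrap edge-stability evaluation, and edge-level
    precision/recall scoring against the gold standard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
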