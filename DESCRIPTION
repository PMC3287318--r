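Package: reefdiv
Title: Diversification Rates and Phylogenetic Community Structure of
    Coral-Reef Fish Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing diversification and community assembly on
    ultrametric chronograms. Implements time-dependent pure-birth (Yule)
    models with constant, piecewise (rate-shift), logistic, and sea-level
    covariate speciation rates, fitted by maximum likelihood and compared by
    AIC; the constant-rate birth-death likelihood; lineage-through-time
    curves with simulation envelopes and per-window rate estimates;
    likelihood-ratio arithmetic for molecular-clock tests; Sorensen
    community similarity; and threshold-truncated phylogenetic community
    structure (Pi_ST) with partial-randomization null models. Includes
    simulators for chronograms under time-varying speciation rates and for
    community occurrence matrices under neutral, habitat-filtered,
    limiting-similarity, and recent-allopatry assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
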