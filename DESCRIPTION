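Package: promothermo
Title: Thermodynamic Models of Cooperative Transcriptional Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium statistical-thermodynamic models of promoter occupancy
    by RNA polymerase under combinatorial control by transcription factors.
    Enumerates promoter occupancy states with Boltzmann statistical weights,
    computes polymerase binding probabilities, and quantifies synergy between
    two activators with the greater-than-additive/less-than-additive difference
    measure. Provides closed-form critical boundaries separating synergistic
    from sub-additive regimes (including the universal three-body cooperativity
    threshold), dose-response crossover and re-entrance analysis for
    double-binding-site promoters, and estimation of cooperativity factors from
    saturation fold-change measurements of reporter assays. Includes a
    command-line interface and a synthetic fixture generator for noisy
    fold-change tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
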