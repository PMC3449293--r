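Package: cspclba
Title: Linear Ballistic Accumulator Analysis of Context-Specific Proportion
    Congruent Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits competing linear ballistic accumulator (LBA)
    parameterizations of flanker-task choice and response-time data to ask
    whether context-specific proportion congruent (CSPC) effects reflect
    shifts in the rate of evidence accumulation ("drift" models) or in the
    amount of evidence required for a decision ("threshold" models).
    Provides closed-form LBA defective densities and likelihoods,
    per-participant maximum-likelihood estimation via particle swarm
    optimization, AIC/BIC model weights and threshold-versus-drift evidence
    ratios, conventional descriptive behavioral statistics, and a synthetic
    flanker-design simulator for parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
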