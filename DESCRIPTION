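Package: depthbias
Title: Sequencing-Depth Bias in Richness Estimates from Denoised Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how the singleton
    handling of amplicon denoising pipelines (sample-wise, pooled, or
    prior-informed processing) interacts with pre- and post-ASV sub-sampling
    to bias richness and alpha-diversity estimates and to induce spurious
    correlations between sequencing depth and richness. Provides a lognormal
    community simulator with error-generated spurious singletons, the
    singleton-threshold abstraction of DADA2/deblur filtering, hypergeometric
    sub-sampling with analytic rarefaction curves, the standard battery of
    alpha-diversity indices (Hill numbers, Chao1, ACE, Good's coverage,
    Margalef, Menhinick), and a twelve-scenario grid engine that summarises
    depth-richness correlations per processing scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
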