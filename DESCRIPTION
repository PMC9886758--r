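Package: plvnet
Title: Phase-Locking Connectivity, Cluster-Based Permutation Inference, and
    Moderated Memory Associations for Source-Space MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for resting-state source-space
    magnetoencephalography linking phase-locking-value (PLV) functional
    connectivity to behaviour. Computes band-limited instantaneous phase,
    epoch-averaged PLV matrices and normalized nodal strength; relates
    strength maps to a behavioural score with a covariate-adjusted
    partial-Spearman cluster-based permutation test (Fisher-Z cluster mass,
    max-cluster permutation null); runs seed-based secondary cluster
    analyses; correlates cluster markers with structural measures under
    false-discovery-rate control; compares groups with covariate-adjusted
    linear models; and fits moderated regressions with Johnson-Neyman
    regions of significance. Includes a synthetic coupled-oscillator cohort
    generator with planted phase-coupled clusters, connectivity-behaviour
    effects and genotype moderation, so the whole pipeline is testable
    without access to subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
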