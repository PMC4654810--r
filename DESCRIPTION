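Package: poly4C
Title: Polymer-Physics Analysis of Multi-Viewpoint 4C-seq Contact Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of multi-viewpoint (PE-)4C-seq chromatin
    contact data grounded in a generalized Gaussian polymer model. Implements
    multiplicative bias-factor estimation by log-linear least squares,
    unbiased contact probability profiles with Gaussian-kernel smoothing,
    differential interacting region (DIR) discovery by windowed Mann-Whitney
    tests with replicate intersection, local chromatin compaction exponents
    from log-log smoothing-spline slopes, spring-constant fitting of 3D DNA
    FISH distance distributions, interval enrichment by permutation, and a
    bead-on-string Gaussian chain simulator that doubles as the null model
    and as a synthetic-data generator.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
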