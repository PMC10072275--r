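Package: nmjCa
Title: Calcium Imaging Analysis of Drosophila NMJ Terminals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of compartment-specific Ca2+ imaging at the
    Drosophila larval neuromuscular junction. Implements power-law photobleach
    correction of fluorescence time series, dF/F evoked-response feature
    extraction, miniature synaptic event detection, translation drift
    registration and ROI trace extraction from multilayer TIFF movies,
    Intermodes histogram thresholding and puncta/ratiometric quantification of
    static confocal images, and the normality-gated statistical comparison
    scheme (Student's t / Mann-Whitney, mixed-effects repeated-measures ANOVA,
    Tukey and Dunnett post-hoc tests) with per-larva datapoints. A synthetic
    data generator produces traces, movies and two-channel images with known
    ground truth emulating cytosolic, ER-lumen and mitochondrial responses of
    wild-type and mutant terminals, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    car,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
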