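Package: topoplast
Title: Electrical Neuroimaging of Event-Related Potential Topographic
    Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reference-free analysis of multi-channel event-related
    potentials (ERPs) in within-subject factorial designs: global field
    power (GFP) and global map dissimilarity (DISS), time-sample-wise
    repeated-measures ANOVA with a minimum-duration significance
    criterion, randomization-based topographic ANOVA (TANOVA),
    agglomerative hierarchical clustering of scalp topographies with
    Krzanowski-Lai model selection, single-subject template back-fitting
    with map-duration statistics, and Spearman brain-behavior
    correlations.  Includes a synthetic ERP generator with known ground
    truth emulating a 2x2x2 stimulation-by-side-by-session somatosensory
    design, so every stage of the pipeline can be validated by recovery
    of planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
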