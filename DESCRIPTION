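Package: chplot
Title: Charge-Hydropathy Plots and Data-Driven Hydropathy Scale Derivation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Whole-protein order/disorder classification by charge-hydropathy
    (C-H) plots. Bundles the Kyte-Doolittle, Guy and IDP-Hydropathy amino-acid
    hydropathy scales with explicit orientation and unit-interval
    normalization, computes per-protein composition, net charge and mean
    hydropathy, and classifies proteins against linear C-H boundaries. Derives
    new hydropathy scales from labelled sequence corpora by training
    class-weighted linear support vector machines on 41-residue window
    composition features with protein-level repeated cross-validation and
    weight averaging, refits whole-protein boundaries, and evaluates with a
    full imbalanced-data metric suite (sensitivity, specificity, balanced
    accuracy, PPV, NPV, F-score, MCC, ROC AUC). Includes scale-vs-scale
    Pearson correlation analysis against amino-acid index collections and a
    synthetic corpus generator with a planted hydropathy direction for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
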