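Package: glandstab
Title: Stability-Informed Histomorphometric Feature Analysis for
    Multi-Site Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts 242 gland-morphology and texture features from
    annotated H&E regions of interest (global graph, gland shape,
    orientation disorder, sub-graph, and Haralick families), quantifies
    each feature's preparation-induced instability (PI) across sites with
    Wilcoxon rank-sum comparisons of non-cancerous regions, gates feature
    selection on stability (PI < 0.25), and evaluates cross-site
    classifier generalization under hold-one-site-out validation.
    Includes lumen-based gland segmentation, Macenko-style stain
    normalization, and a synthetic-data subsystem that emulates
    multi-site H&E regions and feature tables with known discriminative
    and site-shifted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    igraph,
    e1071,
    randomForest,
    png,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
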