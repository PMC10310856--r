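Package: glianet
Title: Network Propagation, Disease Module Discovery and Astrocyte
    Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A proteogenomic-cellular analysis toolkit for
    neurodegenerative disease genetics. Builds a composite
    protein-interaction network from scored and unscored edge tables,
    diffuses GWAS association weights over it with personalized PageRank,
    discovers gene modules by iterative walktrap community detection, and
    scores module significance with Kolmogorov-Smirnov tests under
    Benjamini-Hochberg control. Includes cross-disease module overlap
    (Jaccard grouping), Fisher gene-set enrichment, ROC benchmarking of
    propagation scores against gold-standard gene sets, multi-omics
    triple-overlap candidate selection with the Significance A outlier
    statistic, and quantitative cell morphometrics (form factor,
    distance-binned particle density profiles, area overlap, orientation
    dispersion, track speeds). A synthetic-data module generates planted
    interactomes, omics tables, raster shapes, orientation textures and
    tracks with known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    grDevices,
    minpack.lm,
    EBImage,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
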