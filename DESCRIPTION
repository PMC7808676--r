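Package: cytoshell
Title: Distance-Shell Volumetric Analysis of Receptor Distribution in Single Cells
Version: 0.1.0
Authors@R: person("Maintainer", "Cytoshell", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A 3D volumetric analysis pipeline for quantifying the subcellular
    distribution of punctate fluorescent signal (e.g. receptor or endosome
    markers) in single dividing cells imaged by confocal microscopy.
    Provides single-cell segmentation from z-stacks (Gaussian smoothing,
    scaled Otsu thresholding, morphological cleanup), an exact anisotropic
    Euclidean distance transform, partition of the cell into concentric
    distance shells (membrane-associated, peripheral and deep cytoplasm),
    regional fold-enrichment statistics, object-based Manders' overlap
    colocalization, ventral/dorsal polarity ratios, the associated group
    comparison statistics (one-way ANOVA with Tukey HSD, Fisher exact and
    Pearson chi-squared tests, arcsine square-root transformed t-tests), and
    a ground-truthed synthetic confocal stack simulator used to validate
    every stage by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
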