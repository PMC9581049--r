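Package: kna
Title: K-Neighbourhood Analysis of Single-Molecule Localisation Microscopy Point Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scale-free, per-localisation characterisation of 2D single-molecule
    localisation microscopy (SMLM) point patterns. Each localisation is described
    by its vector of distances to the first K nearest neighbours, normalised by the
    K-th distance, and projected onto a principal-component basis trained on a
    completely spatially random (CSR) point pattern (spatial neighbourhood PCA,
    SNPCA). The resulting per-localisation coordinates (local density, SNPC1,
    SNPC2 and their polar form) support a hue-based visualisation of single
    images, a compositional frequency-table representation for comparing
    ensembles of images (log-ratio ordination, between-component analysis,
    permutation tests for multivariate dispersion and means), and an
    enrichment score for the spatial preference of a second channel such as
    receptor phosphorylation. A ground-truth-annotated simulator of clustered
    SMLM patterns is included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
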