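Package: nirpls
Title: Near-Infrared Chemometric Calibration with PLS and Competitive
    Wavelength Selection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemometric calibration toolkit for near-infrared (NIR)
    diffuse-reflectance spectra against wet-chemistry reference assays,
    built around PLS1 regression.  Provides spectral pretreatments
    (standard normal variate, multiplicative scatter correction,
    Savitzky-Golay smoothing and first derivative), Mahalanobis/Chauvenet
    outlier screening in PCA score space, Kennard-Stone sample-set
    partitioning, 10-fold cross-validated latent-variable selection,
    genetic-algorithm and competitive adaptive reweighted sampling (CARS)
    wavelength selection, and a validation battery (RMSEC/RMSECV/RMSEP,
    Pearson R2, slope, Roy's r2m, y-randomization cR2P).  Includes a
    synthetic NIR spectra generator emulating overlapping hydrogen-bond
    absorption bands with multiplicative and additive scatter, plus the
    radical-scavenging clearance and FRAP standard-curve assay arithmetic
    used to produce reference values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
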