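Package: ficmap
Title: Cortical Surface Mapping of Frontoinsular Cortex from Diffusion Microstructure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the frontoinsular cortex (FI) from multi-shell diffusion MRI by
    fitting gray-matter microstructure models (NODDI with spherical-mean
    acceleration, and free-water-eliminated DTI), projecting the fitted
    parameter volumes onto white/pial cortical surface models with a
    depth-weighted robust sampling scheme, segmenting FI by thresholding the
    smoothed surface maps inside an anterior-insula restriction mask, and
    quantifying parcel volume, surface area and thickness.  Includes cohort
    statistics (test-retest ICC and CoV, Falconer twin heritability,
    skewness-based threshold optimization, standardized behavioral regression
    with Tukey outlier exclusion, Benjamini-Hochberg FDR, delta-BIC, and
    population probability maps) and a synthetic-data module that generates
    icosphere phantoms, multi-shell diffusion signals and twin/retest cohorts
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    minpack.lm,
    pracma,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
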