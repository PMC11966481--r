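Package: corticalmark
Title: Cortical Deficit-Pattern Biomarkers from Regional Homogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building and evaluating functional cortical
    deficit-pattern biomarkers for case-control neuroimaging studies.
    Computes voxelwise regional homogeneity (Kendall's coefficient of
    concordance over 3x3x3 neighborhoods) from 4-D BOLD-like volumes,
    reduces it to bilateral parcel means, derives age- and sex-adjusted
    per-region Cohen's d effect-size maps, tests spatial correlation
    between maps with spin permutations on spherical parcel centroids,
    compares map correlations with Fisher's r-to-z, and scores
    individual subjects against template deficit patterns with the
    Regional Vulnerability Index (RVI). A synthetic-cohort module
    generates toy atlases, 4-D time series with controllable local
    temporal coherence, and regional cohort tables with planted
    effect-size patterns, so the whole pipeline runs end-to-end with
    no external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
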