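Package: bcprofiler
Title: Bacterial Cytological Profiling for Antibiotic Mechanism-of-Action Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bacterial cytological profiling (BCP): segmentation of
    rod-shaped bacteria from multi-channel fluorescence micrographs, per-cell
    morphological and intensity feature extraction, quality-control filtering
    (missing-data removal, within-treatment 5-SD outlier removal, balanced
    subsampling), pairwise principal component analysis with 95% confidence
    ellipses, and a concordance statistic that ranks a query antibiotic's
    mechanism of action against reference antibiotics. Also includes seeded
    synthetic-data generators for feature tables, capsule-cell image scenes,
    microdilution plates and dose-response curves, plus assay arithmetic
    (CFU/mL, broth-microdilution MIC calls, four-parameter logistic IC50
    fitting) and molecular-formula utilities (monoisotopic mass, deprotonated
    ion m/z, degree of unsaturation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
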