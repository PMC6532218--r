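Package: vitroquant
Title: Quantification of Vitronectin Staining Patterns in Brightfield
    Tissue Microarray Cores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital-pathology pipeline for DAB immunohistochemistry of
    extracellular-matrix proteins such as vitronectin in neuroblastoma
    tissue microarray cores. Decomposes RGB brightfield images into
    hematoxylin and DAB optical densities, classifies staining intensity
    into negative/weak/moderate/strong pixel classes, segments nuclei and
    partitions tissue into territorial (intracellular plus pericellular)
    and interterritorial zones by distance-transform banding, and derives
    per-core morphometry (percent stained area by zone, nuclei density,
    H-score). Includes a synthetic core and survival-cohort generator with
    exact ground truth for validation, and the cohort-level statistical
    battery: rank tests against prognostic factors, third-quartile
    dichotomization, Kaplan-Meier/log-rank survival and Cox regression
    with backward Wald elimination.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    survival,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
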