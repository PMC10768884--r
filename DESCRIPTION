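Package: fixelnorm
Title: Individualized Normative Fixel-Based White-Matter Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-patient normative analysis of fibre density and
    cross-section (FDC) measures defined on a shared fixel template.
    Reads and writes the fixel directory image format, reduces per-fixel
    FDC to per-tract means, removes scanner batch effects with a
    parametric empirical-Bayes ComBat model, applies rank-based inverse
    normal transformation, and scores individual patients against a
    normative control cohort as per-tract and per-fixel Z-scores, with a
    hemispheric laterality index and spider-plot visualization.
    Includes a synthetic cohort generator so the full pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    generics,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    patchwork
Config/testthat/edition: 3
RoxygenNote: 7.3.3
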