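Package: octtcfa
Title: Thin-Cap Fibroatheroma Detection and Outcome Analysis from OCT Segmentation Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies lipid plaques on intravascular optical coherence
    tomography (OCT) segmentation label maps (lipid arc and minimum fibrous
    cap thickness measured radially from the lumen centroid), applies
    artefact-based frame and lesion exclusion rules, calls thin-cap
    fibroatheromas (TCFA) with a 3-of-10-consecutive-frames rule at lesion,
    pullback and patient level, and relates TCFA status to two-year clinical
    outcome via Cohen's kappa reader agreement, Kaplan-Meier and Cox
    analyses, and binary-exposure C-statistics with DeLong comparison.
    Includes a calibrated synthetic cohort generator (label masks, reference
    reader calls and proportional-hazards follow-up) so the full pipeline can
    be exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    pROC,
    jsonlite,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
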