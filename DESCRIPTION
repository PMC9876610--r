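Package: gazetraits
Title: Gaze Preprocessing and Trait-Moderation Analysis of Attention to the Eyes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for free-viewing eye-tracking studies of how autistic
    traits and social anxiety modulate attention to the eye region of faces.
    Provides a synthetic gaze-data simulator with recorded ground truth,
    gaze preprocessing (gap interpolation, binocular averaging, dispersion-based
    fixation detection, area-of-interest labelling, trial exclusion rules),
    questionnaire scoring and trial-level eye-looking metrics, moving-average
    epoch time courses, linear mixed models with Satterthwaite Type III tests
    and simple-slope moderation analysis, and a cluster-based permutation test
    for group differences in temporal eye-looking dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
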