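Package: trajsplit
Title: Separating Decision Errors from Action Execution in Mouse-Tracking Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-level analysis of two-choice mouse-tracking
    experiments. Provides trajectory preprocessing (truncation to the
    movement proper, flipping, 101-step time normalization), signed
    curvature measures (area under the curve and maximum absolute
    deviation with the toward-the-wrong-target-positive sign convention),
    a geometry-based vertical-cutoff classifier that separates smooth
    single-step movements from multi-step movements beginning toward the
    wrong target, a cutoff-relaxation sweep of the within-subject effect
    size, pre/post-MAD velocity-profile renormalization, paired
    within-subject statistics (t, Cohen's dz) with a with/without-cutoff
    report, and a seeded minimum-jerk generator of synthetic datasets
    with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
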