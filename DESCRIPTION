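Package: cartilageT2
Title: Voxel-Wise Cartilage T2 Relaxometry, Laminar Morphometry and
    Pre/Post-Loading Mixed-Effects Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative MRI analysis of knee articular
    cartilage around an acute loading experiment: mono-exponential T2
    mapping of multi-echo spin-echo series with first-echo exclusion,
    distance-based splitting of cartilage regions into superficial and
    deep laminae, distance-transform cartilage thickness morphometry on
    resampled grids, and linear mixed-effects group-by-time contrasts
    with Sidak adjustment. Includes a synthetic-data module that
    generates multi-echo knee-like phantoms (two-layer T2 structure,
    bone interface, stimulated-echo artifact, Rician noise) and
    simulated pre/post cohorts, plus a configuration-driven pipeline
    with NIfTI-1 and CSV interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
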