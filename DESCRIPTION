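Package: keratopower
Title: Corneal Power and Adjusted Keratometric Index in Keratoconus After Crosslinking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Paraxial corneal-power calculations for keratoconus eyes treated
    with accelerated corneal collagen crosslinking (CXL). Implements the
    keratometric and Gaussian thick-lens corneal powers under the Gullstrand
    and Le Grand schematic eye models, the exact keratometric index that makes
    both agree, and a piecewise-linear adjusted keratometric index calibrated
    over the post-CXL curvature domain so that single-surface keratometry
    recovers total corneal power within +/- 0.8 D. Includes an exhaustive
    simulation sweep of the post-CXL domain, a synthetic-cohort generator
    emulating published clinical summaries, and Bland-Altman / correlation /
    paired-test agreement machinery for comparing power estimates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
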