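Package: shiftsense
Title: Contextualized Psychophysiology of Wearable Sensor Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed feature extraction and mixed-model trajectory analysis for
    wrist-worn multichannel biosensor recordings collected during operational work
    shifts, with fusion against computer-aided dispatch (CAD) event logs and
    automated vehicle locator (AVL) tracks. Implements tonic/phasic electrodermal
    activity decomposition with polynomial smoothing filters, skin-conductance
    response peak detection, accelerometer activity counts, interbeat-interval
    quality assessment, per-second call-phase event coding, and small-sample
    linear mixed models with random intercepts and slopes (REML estimation,
    Satterthwaite or Kenward-Roger degrees of freedom). A synthetic shift
    generator produces sensor streams with stress-linked structure plus matching
    CAD and AVL records so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    nlme
Suggests:
    pbkrtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
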