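Package: pjaplan
Title: Biomechanical Planning of the Proximal Junctional Angle in Scoliosis Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Procedural planning tool for proximal junctional kyphosis (PJK)
    after long posterior instrumentation and fusion surgery. Simulates
    loading-angle-dependent stress in the cephalad intervertebral disc of the
    upper instrumented vertebra with a linear-elastic tetrahedral
    finite-element model, summarises pre- versus post-operative stress changes
    over eight anatomical disc subregions, models PJK risk with a two-layer
    fully connected network trained by Adam, ranks features by the DX
    discrimination score, and inverts the learned model to recommend an
    optimal proximal junctional angle (PJA) per patient. Includes a packaged
    twelve-patient cohort table, a synthetic-cohort generator with a known
    risk mechanism for parameter-recovery testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
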