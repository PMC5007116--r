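Package: rpmpet
Title: Reference-Region Kinetic Quantification for Dynamic TSPO PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantification chain for dynamic brain PET studies
    that use a reference-tissue approach without an anatomical reference
    region: forward kinetic simulation (tri-exponential input function,
    two-tissue compartment model, simplified reference tissue model, frame
    averaging and count-statistics noise), supervised cluster analysis with
    four kinetic classes (SVCA4) to extract a reference-tissue input curve,
    basis-function simplified reference tissue model fitting with a vascular
    correction (RPM-Vb) producing binding-potential parametric maps, ROI
    aggregation, and the accompanying group-comparison and power statistics.
    Includes a synthetic cohort and dynamic phantom generator so the whole
    pipeline can be exercised and validated without access to scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    car,
    RNifti,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
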