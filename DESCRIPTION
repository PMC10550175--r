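Package: drillscore
Title: Voxel-Based Outcome Scoring for Virtual Dental Drilling Simulators
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated assessment of drilling outcomes in virtual dental
    surgery training. Represents tooth material as voxel occupancy grids
    built from metaball sphere sets, classifies an actual drilling outcome
    against an expert-approved ideal outcome into true/false
    positive/negative voxel counts, and scores the result with the Dentist
    metric, a rescaled weighted combination of precision and sensitivity
    expressed on the 0-15 clinical rubric scale (0 = ideal). Includes an
    F1 baseline and a suite of standard binary-classification metrics,
    essential-outcome selection for expert review, inter-rater agreement
    statistics (Cohen's kappa, intraclass correlation, the
    information-based measure of disagreement), a procedural molar phantom
    and drilled-outcome generator for fully synthetic end-to-end runs,
    and pre/post learning-gain analytics with hand-tool calibration and
    gaze-distance utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
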