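Package: dscqc
Title: Automated Quality Control for DSC-MRI Signal-Time Courses
Version: 0.1.0
Authors@R:
    person("Quality Control", "Maintainers", email = "dscqc@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise quality assessment of dynamic susceptibility contrast
    (DSC-) MRI perfusion data. Detects the baseline and post-bolus plateaus of
    a signal-time course, computes four quantitative quality measures (signal
    drop-to-noise ratio, normalised gamma-variate fit RMSE, first-pass FWHM
    and percentage signal recovery), calibrates pass/fail thresholds from
    qualitative-review labels by stratified k-fold cross-validation, trains
    and compares five classifier families on the measures, computes interrater
    agreement statistics, and produces per-voxel quality maps from 4D NIfTI
    volumes. Includes a synthetic signal simulator with injectable artifacts
    so the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
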