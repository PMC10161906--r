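# dscqc — automated quality control for DSC-MRI signal-time courses

Dynamic susceptibility contrast (DSC-) MRI estimates brain perfusion by
imaging the first transit of a gadolinium bolus; every voxel contributes a
signal-time course whose quality decides whether the derived blood-volume
and blood-flow values can be trusted. The recommended quality check —
visual review of individual courses — cannot scale to the tens of thousands
of voxels in one acquisition. `dscqc` automates it, for MR physicists and
imaging researchers who need voxel-wise, protocol-portable QC:

* **Segmentation** of each course into baseline, first pass and post-bolus
  plateau by a moving-mean vs cumulative-mean divergence rule (applied
  forwards and, for the post-bolus start, backwards).
* **Four quantitative measures** per course:
  * signal drop-to-noise ratio `SDNR = SignalDrop / SD(baseline)`, where the
    signal drop is the mean baseline minus the mean of the first-pass
    minimum and its two neighbours;
  * RMSE of a simplified gamma-variate fit `y(t) = c − K t^α e^(−t/β)` over
    the first pass (`c` fixed at the baseline mean), normalised to the
    first-pass drop area (units 1/s);
  * FWHM of the first pass, in seconds, at half the signal drop;
  * percentage signal recovery `PSR = 100 · T2*Recovery / SignalDrop`.
* **Threshold calibration** from binary qualitative-review labels by
  stratified 10-fold cross-validation: sensitivity-equals-specificity
  crossing thresholds for SDNR/RMSE, passed-value ranges for FWHM/PSR,
  fold-averaged with per-fold provenance.
* **Five classifier families** (CART tree, squared-hinge SVM, bagged trees,
  random forest, ridge logistic regression) trained on the four measures
  with nested cross-validation (outer 10-fold metrics, inner 5-fold
  hyperparameter search) and compared by classification error.
* **Agreement statistics**: sensitivity/specificity/precision/
  classification error, tie-aware ROC AUC, percentage disagreement and
  Cohen's kappa with subgroup reports.
* **Synthetic data**: a gamma-variate bolus simulator with tunable noise,
  recovery, protocol mix (TR 1.3–4.9 s) and injectable artifacts (motion
  spikes, noisy first pass, narrow bolus, shallow drop), emitting
  ground-truth labels — the package's entire test bed, since no patient
  data are deposited.
* **NIfTI quality maps**: per-voxel pass/fail/NaN grids with provenance and
  pass-rate summaries, plus a CLI (`inst/cli/dsc-qc`) covering
  `simulate | extract | calibrate | train | predict | map | agreement`.

The methods vignette (`vignettes/dsc-quality-control.Rmd`) documents the
model, the numerical choices and the limits of what the synthetic tests
establish.

## Worked example

```r
library(dscqc)

## a 600-course synthetic cohort labelled by the rule "true SDNR >= 8"
cohort   <- simulate_cohort(n = 600, seed = 42, spec = cohort_spec_sdnr_recovery())
features <- cohort_feature_table(cohort, min_baseline = 15, k_sigma = 1.5)

## calibrate thresholds against the labels
thresholds <- calibrate_kfold(features, k = 10, seed = 42)
thresholds
#> <threshold_set (k = 10): SDNR >= 7.27, RMSE <= 0.0107,
#>   FWHM in [8.92, 21.9] s, PSR in [83.5, 119]%>
print(thresholds$metrics, digits = 2)
#>   measure sensitivity specificity precision classification_error  auc
#> 1    sdnr        0.92       0.926      0.93                  7.5 0.98
#> 2    rmse        0.77       0.785      0.79                 22.0 0.81
#> 3    fwhm        0.99       0.064      0.52                 47.2 0.63
#> 4     psr        0.99       0.050      0.51                 47.7 0.61
```

The calibrated SDNR cut-off (7.27) recovers the generating boundary (8)
within measurement bias, with held-out sensitivity and specificity ≈ 0.93;
the labels ignore FWHM/PSR in this world, so their range rules pass almost
everything (sensitivity ≈ 1, specificity ≈ 0) — exactly the behaviour
expected of one-sided "range of passed values" rules on uninformative
measures.

```r
## classifier comparison on a multi-protocol cohort with artifacts
multi <- simulate_cohort(n = 300, seed = 42)
feats <- cohort_feature_table(multi)
ok <- complete.cases(feats[, c("sdnr", "rmse_norm", "fwhm_s", "psr_pct")])
cmp <- compare_classifiers(feats[ok, ],
                           specs = lapply(c("binary_tree", "random_forest",
                                            "logistic_regression"),
                                          classifier_spec),
                           k = 10, seed = 42)
cmp
#>                family sensitivity specificity precision classification_error   auc
#> 1         binary_tree       0.940       0.467     0.929                 11.9 0.863
#> 2       random_forest       0.981       0.550     0.941                  7.3 0.930
#> 3 logistic_regression       0.993       0.183     0.897                 10.7 0.807
#> lowest classification error: random_forest

## voxel-wise quality map for a 4D NIfTI phantom
ph <- tempfile(fileext = ".nii")
write_phantom(grid = c(8, 8, 1), n_dynamics = 40, tr_seconds = 1.5,
              sigma = 30, seed = 42, path = ph)
vol  <- load_dsc_volume(ph)
qmap <- make_quality_map(vol, "threshold",
                         thresholds = read_thresholds(
                           system.file("extdata", "default_thresholds.json",
                                       package = "dscqc")),
                         measure = "sdnr")
qmap
#> <quality_map [threshold:sdnr]: 19/36 valid voxels, 73.68% passed>
```

The phantom's true peak drop rises along x, so the low-SDNR columns fail
the shipped SDNR ≥ 7.6 rule and the summary reports the pass rate among
voxels with a detectable bolus (the zero-signal border is masked out as
NaN). Combining the four measures (random forest) beats any single
threshold on the artifact-laden cohort, mirroring the motivation for
classifier-based QC.

The shipped `inst/extdata/default_thresholds.json` (SDNR 7.6, RMSE 0.019,
FWHM 3–19 s, PSR 42.9–130.4%) contains published cohort-specific values;
recalibrate for your own protocol.

## Conventions

* Dynamic (time) indices are 1-based in all reports; spatial voxel indices
  are 0-based in machine outputs, matching the volume's array order.
* "Accepted" (label 1) is the positive class in every metric.
* All randomness derives from a single integer seed; identical inputs and
  seed reproduce results bit-for-bit.

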