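{
  "comment": "Published cohort-specific defaults calibrated on 1027 qualitatively reviewed paediatric signal-time courses. Protocol-dependent: recalibrate with calibrate_kfold() for any new scanner/protocol.",
  "sdnr_min": 7.6,
  "rmse_max": 0.019,
  "fwhm_range": [3, 19],
  "psr_range": [42.9, 130.4],
  "k": 10,
  "seed": null
}
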