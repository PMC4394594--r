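{
  "_comment": "Published tree-dependent results that require the external supertree sample (1,000 trees from birdtree.org; study deposit Dryad doi:10.5061/dryad.2p31f). These are NOT recomputed by the test suite; inst/scripts/reproduce_published.R documents the exact recipe. Desk-reproducible quantities (the PCO spectrum) live in the test suite instead.",
  "varpart_representative": {
    "AR": 0.065, "M": 0.033, "AR+M": 0.082,
    "AR|M": 0.050, "M|AR": 0.016, "AR^M": 0.017, "residual": 0.918
  },
  "varpart_bounds": {
    "AR": [0.057, 0.073], "M": [0.022, 0.041], "AR+M": [0.070, 0.092],
    "AR|M": [0.041, 0.057], "M|AR": [0.011, 0.020],
    "AR^M": [0.011, 0.023], "residual": [0.908, 0.930]
  },
  "lambda_mean": 0.67,
  "rda_axis1_eigenvalue": 4.46e-4,
  "rda_axis1_relative": 0.083,
  "rda_axis2_relative": 0.026,
  "fitted_ar_ichthyornis": 7.8,
  "fitted_ar_parargornis": 7.3,
  "root_ar": 7.6
}
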