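{
  "modality": "swe",
  "selected_indices": [518, 532, 565, 719],
  "coefficients": [-0.3666784, -1.4319200, -0.4749501, -0.2671713],
  "intercept": 2.496014,
  "threshold": -0.24,
  "lambda": null,
  "orientation": "higher_is_malignant",
  "standardized": false,
  "seed": null,
  "note": "Published shear-wave elastography rad-score reference signature; shipped to validate rad-score arithmetic against its printed coefficients."
}
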