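# Example pipeline configuration: a desk-scale synthetic experiment.
# See ?msifuse::read_pipeline_config for every recognized key.
seed: 7
generator:
  image_size: [64, 64]
  n_per_class: {sirloin: 40, flank: 32, shank: 39}
glcm:
  levels: 64
  distance: 1
  angles: [0, 45, 90, 135]
  symmetric: true
  average_angles: true
spectral:
  rgb_bands_nm: [680, 570, 500]
split: {n_calibration: 89, n_prediction: 22}
svm_c: 0.6
rf_n_trees: 160
cv_folds: 10
feature_sets: [MS, CIELAB, Texture, MS + Texture, CIELAB + Texture,
               MS + Texture + CIELAB]
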