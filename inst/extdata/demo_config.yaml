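# Small demonstration pipeline: three fibrosis grades, two maps each,
# moderate air-pocket contamination, 5-fold CV.
seed: 5
output_dir: ramgrade_demo
synthetic_data:
  grade_levels: [0, 0.3, 1]
  n_maps_per_grade: 2
  points_per_map: [18, 24]
  air_pocket_rate: 0.4
  n_channels: 200
classify:
  response: fibrosis
  folds: 5
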