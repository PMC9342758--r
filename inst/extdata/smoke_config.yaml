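# Desk-scale end-to-end configuration: a 3 km x 3 km landscape, 5 animals,
# ~50 locations each. Runs the full pipeline in well under 5 minutes.
seed: 1
output_dir: selscape_smoke_out
landscape:
  n_rows: 100
  n_cols: 100
  cell_size: 30
  target_composition: [0.54, 0.35, 0.04, 0.02, 0.05]
  smoothing_length: 200
  n_major_roads: 2
  n_minor_roads: 3
covariates:
  window_radius: 150
rsf:
  form: log_linear
  intercept: 0
  coefs:
    dist_agriculture: 0.003
    dist_forest_signed: -0.002
  sex_coef: 0
telemetry:
  n_individuals: 5
  sex_split: [3, 2]
  mean_hr_area: 502655    # pi * 400^2: availability radius 400 m
  n_points_mean: 50
  n_points_sd: 5
  n_points_min: 30
  location_error: 20
ranges:
  iso_level: 0.95
  n_grid: 120
design:
  ratios: [1, 2, 5, 10, 20]
  epsilon: 0.05
  ratio: 10
forest:
  grid:
    n_trees: [50]
    mtry: [2, 4]
    sample_fraction: [0.623]
  min_node: 5
interpret:
  n_grid_pdp: 10
  n_bins: 10
  n_reps: 1
validate:
  run: true
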