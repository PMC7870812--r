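# Demo study configuration: a 100 x 100 synthetic landscape with the
# eight standard land-use classes, 20 synthetic bird-like species, and
# two climate scenarios of contrasting severity run in decadal steps
# 2020-2070. All keys omitted here fall back to the package defaults
# (see ?default_config); unknown keys are rejected.
seed: 42
output_dir: cluesdm_output

grid:
  n_rows: 100
  n_cols: 100
  cell_area: 1.0        # km^2 per cell

species:
  n_species: 20
  n_presences: 300
  biased: true          # occurrences follow observer effort

sdm:
  n_background: 2000
  folds: 5
  min_records: 20
  auc_threshold: 0.7
  importance_threshold: 1

scenarios:
  low:                  # mild-forcing pathway
    severity: 0.3
  high:                 # strong-forcing pathway
    severity: 1.0
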