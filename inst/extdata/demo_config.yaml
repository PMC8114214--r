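# Demo configuration for run_pipeline(): a scaled-down three-cell-line,
# four-replicate synthetic immunopeptidome. Any entry omitted here falls
# back to default_run_config().
seed: 1
synth:
  shared_fraction: 0.1
  n_proteins: 300
  neural_fraction: 0.1
  cell_lines:
    fibroblast: {n_unique: 1500, n_replicates: 4, detection_prob: 0.5, p3_leucine: 0.45}
    DFT1_IFNg: {n_unique: 1100, n_replicates: 4, detection_prob: 0.5, p3_leucine: 0.35}
    DFT2: {n_unique: 600, n_replicates: 4, detection_prob: 0.5, p3_leucine: 0.45}
repertoire: {min_len: 7, max_len: 15}
motif:
  lengths: [8, 9]
allotype:
  n_groups: 3
  abundance: [0.5, 0.3, 0.2]
  n_peptides_per_replicate: 500
  presence_threshold: 3
  n_replicates: 4
pocket:
  pocket: F
  cutoff: 0.93
  top_k: 3
  adjacent_radius: 1
  n_db: 50
  seq_length: 182
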