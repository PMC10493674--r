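# Demo pipeline configuration over the shipped synthetic scenario.
out_dir: braincomm_demo
seed: 1
n_cells_per_type: 60
n_genes: 220
n_subdatasets_per_group: 3
signal_fold: 8
n_planted: 6
reps: 50
k_max: 5
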