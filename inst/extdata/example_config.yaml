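pixel_size: 0.1
gate_min: 0.4
gate_max: 2.0
coloc_cutoff: 0.5
positive_threshold: 6
frap_eval_time: 60.0
alpha: 0.05
seed: 1
per_cell_threshold: no
poly_order: 2
autofluorescence: 0.0
synth: []
n_images: 3
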