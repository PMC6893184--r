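# Example experiment: default B. rapa-like design, boosted vs normal.
# Keys mirror recsel::experiment_config().
species: brapa
scenarios: [normal, boosted]
n_replicates: 20
base_seed: 1
n_qtl_per_chrom: 200
scheme: Fn
pop_size: 250
n_selected: 5
n_generations: 20
selection_mode: genomic
h2: 0.5
recalibration: every_4
markers_per_chrom: 200
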