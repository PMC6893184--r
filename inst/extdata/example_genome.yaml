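# Example synthetic-genome configuration (recsel::read_genome_config).
# A small 3-chromosome genome with a cold pericentromere on each.
species: brapa
GL_normal: [80, 95, 60]
GL_increased: [240, 280, 180]
PL: 35
pericentromere_center: 0.5
pericentromere_width: 0.4
cold_rate_frac: 0.02
gene_density_cold_frac: 0.3
genes_per_chrom: 2000
seed: 7
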