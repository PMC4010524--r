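# Example metadraft pipeline configuration.
# Any key omitted here keeps its package default; unknown keys are rejected.
seed: 1
outdir: metadraft_out
min_contig_len: 5000
min_genes: 3
k: 4
K: 3
ani_min_identity: 50
ani_min_cov: 0.7
species_cutoff: 94.0
island_min_len: 15000
island_density_ratio: 0.2
recruit_window: 1000
recruit_step: 500
gcskew_window: 25000
gcskew_step: 1000
rrna_min_aln_len: 100
rrna_genus_identity: 95
rrna_floor_identity: 80
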