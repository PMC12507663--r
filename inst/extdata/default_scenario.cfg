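n_genes = 100
gene_length_codons = 300
fixed_diff_density = 0.02
pi_s_targets = ibericus=0.00045,structor_wild=0.00140,structor_clonal=0.00027
pi_n_over_pi_s_targets = ibericus=0.21,structor_wild=0.21,structor_clonal=0.43
clonal_divergence = 0.005
n_haplotypes = ibericus=40,structor_wild=40,structor_clonal=40
mito_length = 2000
mito_divergence = 0.05
depth_mean = 20
quality_model = mean=60,sd=10
genotype_error = 0
seed = 1
composition = worker,ibericus,clonal,144
composition = worker,ibericus,wild,20
composition = male,structor,clonal,24
composition = male,structor,wild,53
composition = queen,ibericus,none,100
composition = queen,structor,none,27
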