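# Demonstration configuration: a small synthetic supermatrix simulated on
# the T1 backbone, followed by every analysis stage.  Sized to complete on
# a single CPU in a few minutes.
seed: 42
supermatrix:
  backbone: T1
  n_genes: 30
  mean_length: 60
  rate_sd: 0.4
  completeness: 0.9
  internal_bl: 0.05
  terminal_bl: 0.2
  model:
    type: poisson
    alpha: 0.8
    ncat: 4
delta_pl:
  enabled: true
fclm:
  enabled: true
  max_quartets: 10000
au_test:
  enabled: true
  replicates: 1000
mp_jackknife:
  enabled: true
  replicates: 50
  deletion: 0.36
quartet_tree:
  enabled: true
  n_loci: 100
  n_taxa: 7
  coalescent_scale: 2
asr:
  enabled: true
  generations: 4000
  burnin: 1000
  thin: 10
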