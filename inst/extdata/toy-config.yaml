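# Small end-to-end configuration: a 12-antibody, 4-cohort synthetic study.
seed: 7
outdir: ppinet-toy-out
synthetic:
  n_antibodies: 12
  density: 0.18
  phospho_fraction: 0.25
  multi_gene_fraction: 0.15
  cohort_sizes:
    COHORT01: 80
    COHORT02: 60
    COHORT03: 50
    COHORT04: 45
  noise_sd: 0.1
  heterogeneity: 0.3
  n_lists: 24
  n_top_level: 6
methods:
  - pearsoncor
  - spearmancor
  - simpleparcor
  - genenet
  - glasso
  - ridgenet
  - lassonet
  - elasticnet
  - plsnet
  - aracne.a
  - aracne.m
  - clr
  - mrnet
recall_max: 0.1
top_k: 6
candidate_thresholds:
  from: 5
  to: 60
  by: 5
n_groups: 3
n_modules: 3
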