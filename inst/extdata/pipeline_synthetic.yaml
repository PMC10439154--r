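# Example end-to-end configuration on a small synthetic river. Stages run in
# dependency order; outputs and a digest manifest are written under out_dir.
seed: 7
out_dir: results/pipeline_demo
synthetic:
  n_stations: 30
  n_groups: 1
  clones_per_group: 2
  true_lag: 1
  n_noise_taxa: 30
  library_size: 20000
tasks: [prevalence, ordination, thresholds, screening, networks]
prevalence:
  rank: Genus
  n_top: 6
ordination:
  rank: Phylum
  alpha: 0.05
  n_perm: 199
thresholds:
  grid_step: 0.2
screening:
  task: classification
  n_runs: 6
  max_candidates: 8
networks:
  percentile: 50
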