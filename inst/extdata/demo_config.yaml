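# Demo configuration for the synthetic end-to-end run.
# Omitted keys fall back to the packaged defaults (see read_pipeline_config).
genome:
  chromosomes:
    chr1: 3000000
    chr2: 1200000
  window_size: 250
  cpg:
    background_mean: 3
    cgi_mean: 16
    cgi_len: 4
genes:
  n_genes: 30
  n_coupled: 4
  n_focal: 4
  chrom: chr2
  offset: 20000
  spacing: 30000
  promoter_flank: 2000
methylome:
  baseline_beta: 0.8
  cgi_beta: 0.1
  baseline_sd: 0.08
  noise_sd: 0.03
  focal_hyper_delta: 0.45
  rdmr_b0: 0.15
  coupling_slope: 0.05
  lhb:
    - chrom: chr1
      start: 500000
      end: 1700000
      delta: -0.30
cohort:
  n_models: 22
counts:
  depth: 30
  o: 2
  f_max: 30
  k: 10
  dispersion: 0.05
expression:
  coupling: -4
  noise_sd: 0.1
validation:
  n_pairs: 18
  group_means: [7.4, 13.9]
  group_sd: 4
  hazard_ratio: 3
  censor_rate: 0.3
thresholds:
  dmr_fdr: 1.0e-4
  dmr_delta: 0.20
  rdmr_p: 0.01
  corr_p: 0.05
  lhb_tile: 100000
  lhb_min_size: 1000000
  lhb_min_drop: 0.20
seed: 17
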