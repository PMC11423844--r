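# Example pipeline configuration (see load_run_config / run_pipeline)
seed: 1
outdir: jurisdea-output
stages: [describe, dea, rf, regional]
synthetic:
  n_jurisdictions: 60
  years: [2009, 2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017, 2018, 2019, 2020]
bootstrap:
  B: 100
  ci_level: 0.95
determinants:
  n_trees: 500
  vars_per_split: 5
  cv_folds: 10
  cv_repeats: 3
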