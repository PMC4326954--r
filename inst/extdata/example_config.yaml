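# Example pipeline configuration (synthetic cohort).
# For real data replace `synthesis` with:
#   inputs:
#     phenotypes: phenotypes.csv
#     lifespans: lifespans.csv
#     annotations: effects.csv
synthesis:
  seed: 1
  n_strains: 30
  n_animals_per_strain_sex: 8
  age_groups: [6, 12, 18, 24]
  lifespan_mean: 26
  lifespan_sd: 5
  short_lived:
    n_strains: 6
    lifespan_cap: 18
    dropout: false
thresholds:
  alpha: 0.05
  r_min: 0.2
  qualifier_margin: 0.15
  volatile_ages: [18, 20, 24]
  ties: efron
excluded_strains: auto   # short-lived subset (synthetic) / lifespan quantile
out: agemarkers_out
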