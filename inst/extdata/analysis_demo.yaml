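# Demo analysis: three simulated species-like populations run through the
# full pipeline. Keys mirror analysis_config(); each simulation block mirrors
# simulation_config().
seed: 1
min_age_count: 5
min_side: 25
cutoff_overrides:
  WA.F: 18
simulation:
  - n_individuals: 300
    species_profile: annual
    n_years: 38
    seed: 101
  - n_individuals: 300
    species_profile: biennial_short
    n_years: 38
    seed: 102
  - n_individuals: 300
    species_profile: biennial_yearlong
    n_years: 38
    seed: 103
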