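# Demo generative configuration: a grey-headed-albatross-like biennial
# population with a survival cost of quality (selective disappearance) and a
# terminal improvement. Keys mirror simulation_config().
n_individuals: 400
species_profile: biennial_short
n_years: 40
seed: 42
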