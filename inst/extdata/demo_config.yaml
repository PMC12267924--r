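# bundled demo: a small synthetic world exercising every pipeline stage
synthetic:
  n_species: 600
  n_countries: 24
  n_families: 40
  paradox_target: 0.273
  seed: 7
include_nt: false
cell_size_deg: 0.7
ci_level: 0.95
n_permutations: 199
seed: 7
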