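# Biomass on C8, C9, C11, C12; disease compounds C11 and C12.
objective_weights:
  C8: 1
  C9: 1
  C11: 1
  C12: 1
default_flux_upper: 10
healthy_ranges:
  C9: [10, 15]
  C10: [10, 15]
  C11: [10, 15]
  C12: [0, 1]
disease_compounds: [C11, C12]
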