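# Alternative healthy ranges under which the disease is curable
# without side effects.
objective_weights:
  C8: 1
  C9: 1
  C11: 1
  C12: 1
default_flux_upper: 10
healthy_ranges:
  C9: [10, 15]
  C10: [5, 15]
  C11: [15, 20]
  C12: [10, 15]
disease_compounds: [C11, C12]
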