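# Illustrative 12-metabolite / 8-reaction network.
# R7 is the stoichiometry-consistent form C6 + 3 C7 -> 2 C11 + 3 C12
# (see ?toy_network for why the published "C6 + 3 C6" left side is corrected).
reaction_id	equation	enzymes	flux_upper
R1	2 C1 + C2 -> C5 + C6	E1	10
R2	4 C3 -> 3 C6 + C7	E2	10
R3	3 C2 -> C8	E3	10
R4	C4 -> 2 C8	E4	10
R5	2 C5 -> 3 C9	E5	10
R6	2 C6 -> C10 + 2 C11	E6	10
R7	C6 + 3 C7 -> 2 C11 + 3 C12	E7	10
R8	2 C8 -> 3 C12	E8	10
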