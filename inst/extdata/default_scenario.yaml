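# Default study design: both formulations, four dose levels each, three
# levels of inter-individual variability, 500 subjects per cell, endpoints
# evaluated over 0-90 min post-dose at 0.25-min resolution.
formulations: [sc, sl]
doses_mg:
  sc: [1, 2, 3, 4]
  sl: [20, 30, 40, 50]
cv_levels: [0.15, 0.30, 0.45]
n_subjects: 500
seed: 1001
t_end_min: 90
dt_min: 0.25
mcic: 3.25
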