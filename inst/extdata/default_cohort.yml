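schema_version: 1
n_per_cell: 85
n_rounds: 20
b0: -0.9
b_strat: 0.35
b_emo_g: 0.5
b_emo_e: 0.0
b_recip: 0.7
b_expect: 0.5
b_first: 1.6
b_last: -0.9
sigma_u: 1.0
a0: 0.0
a_exp: 60.0
a_emo: 8.0
exp_noise_sd: 16.0
exp_between_sd: 8.0
emotion_temperature: 1.5
post_task:
  demand_mean:
    extortion: 3.05
    generosity: 3.5
  genuineness_mean:
    extortion.cooperative: 3.6
    extortion.competitive: 4.4
    generosity.cooperative: 5.5
    generosity.competitive: 4.4
  sd: 1.6
seed: 1
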