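{
  "hours": 24,
  "controller": {"x_set": 0.8, "y_max": 1, "dt_hours": 0.5, "alpha": 0.7, "k_init": 0},
  "noise": {"od_cv": 0.05, "vol_cv": 0.02, "seed": 42},
  "plates": [
    {"plate": "P1", "od0": 0.1, "volume_ul": 175, "k": 0.7, "expression_factor": 1000, "rows": 8, "cols": 12}
  ]
}
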