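{
  "data_set": 1,
  "regression": {
    "b1": -1.600,
    "b10": 3.9e-06,
    "b2": 1.110,
    "b21": -0.514,
    "b4": -1.570,
    "b41": -0.100,
    "b43": -1.78e-05,
    "b5": 19.970,
    "b52": -0.6564,
    "s_a": 0.62,
    "s_T1": 0.124,
    "s_b": 0.07,
    "s_T2": 1.62,
    "t1_link": "log",
    "noise_convention": "sd"
  },
  "division": {
    "alpha": 29.29
  }
}
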