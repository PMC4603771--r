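{
  "data_set": 3,
  "regression": {
    "b1": -1.75,
    "b10": 5.01e-06,
    "b2": 1.18,
    "b21": -0.349,
    "b4": -1.8,
    "b41": -0.0151,
    "b43": -2.12e-05,
    "b5": 19.91,
    "b52": -0.40,
    "s_a": 0.35,
    "s_T1": 0.15,
    "s_b": 0.09,
    "s_T2": 2.53,
    "t1_link": "log",
    "noise_convention": "sd"
  },
  "division": {
    "alpha": 35.41
  }
}
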