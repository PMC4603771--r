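{
  "data_set": 4,
  "regression": {
    "b1": -2.10,
    "b10": 1.39e-05,
    "b2": 1.41,
    "b21": -0.1123,
    "b4": -1.9,
    "b41": -0.0437,
    "b43": -3.16e-05,
    "b5": 20.90,
    "b52": -0.37,
    "s_a": 0.485,
    "s_T1": 0.11,
    "s_b": 0.11,
    "s_T2": 2.16,
    "t1_link": "log",
    "noise_convention": "sd"
  },
  "division": {
    "alpha": 25.95
  }
}
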