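{
  "data_set": 2,
  "regression": {
    "b1": -3.37,
    "b10": 7.82e-05,
    "b2": 4.81,
    "b21": 0.0465,
    "b4": -1.7,
    "b41": -0.0157,
    "b43": -9.89e-05,
    "b5": 18.93,
    "b52": -0.75,
    "s_a": 0.45,
    "s_T1": 2.00,
    "s_b": 0.08,
    "s_T2": 2.54,
    "t1_link": "identity",
    "noise_convention": "sd"
  },
  "division": {
    "alpha": 15.79
  }
}
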