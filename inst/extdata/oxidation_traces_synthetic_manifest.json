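{
  "protection": 2,
  "k_control": 0.05,
  "k_treated": 0.0107426638164367,
  "plateau_fraction": 0.2,
  "f0": 1000,
  "duration": 60,
  "cadence": 5,
  "noise_sd": 0.005,
  "seed": 11,
  "calibration": "endpoint",
  "ox_control_noiseless": 0.760170345305709
}
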