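{
  "gp_target": 0.25,
  "w": 0.630391220935226,
  "band_centers": [440, 490],
  "band_sd": 18,
  "total_intensity": 1000,
  "noise_sd": 0,
  "seed": 1
}
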