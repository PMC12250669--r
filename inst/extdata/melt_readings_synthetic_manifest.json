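{
  "r_gel": 0.3,
  "r_fluid": 0.07,
  "t_half": 39.3,
  "slope_width": 1.2,
  "g_true": 1.1,
  "noise_sd": 0.005,
  "n_replicates": 2,
  "temperature_grid": [20, 23, 26, 29, 31, 33, 35, 37, 39, 41, 43, 45, 47, 49, 51],
  "i_vv_scale": 1000,
  "seed": 11,
  "r_true": [0.29999997618641, 0.299999709891418, 0.299996465803806, 0.299956952073183, 0.299772266227124, 0.298799371090482, 0.293782661106403, 0.270506240353721, 0.199300595203733, 0.114892475713183, 0.0800739994747861, 0.0719728216451538, 0.0703752284951352, 0.0700709654161345, 0.0700134069911021]
}
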