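{
  "prevalence": 2.06,
  "pop": 1180553,
  "theta_m": 20.71,
  "theta_b": 5.37,
  "theta_d": 2.42,
  "theta_w": 71.50,
  "b_m": 33.3,
  "b_b": 30.0,
  "psi_m": 27.0,
  "psi_b": 26.0,
  "psi_d": 10.0,
  "psi_w": 1.0,
  "k_m": 0.77,
  "k_b": 0.39,
  "k_d": 0.53,
  "k_w": 2.91,
  "gamma_w": 1.50,
  "mortality_scale": 1.0
}
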