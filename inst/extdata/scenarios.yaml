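# Simulation scenario presets for simulate_delivery()/error_model().
nominal:            # fleet-level SDs observed on the modelled system
  sys_sd_x_mm: 0.189
  sys_sd_y_mm: 0.175
  rand_sd_x_mm: 0.049
  rand_sd_y_mm: 0.044
  mu_sd: 2.0e-4
  size_sd_x_mm: 0.131
  size_sd_y_mm: 0.166
noisy:              # 3x the nominal SDs
  sys_sd_x_mm: 0.567
  sys_sd_y_mm: 0.525
  rand_sd_x_mm: 0.147
  rand_sd_y_mm: 0.132
  mu_sd: 6.0e-4
  size_sd_x_mm: 0.393
  size_sd_y_mm: 0.498
pathological:       # gross layer shifts that must trip the 1 mm tolerance
  sys_sd_x_mm: 5.0
  sys_sd_y_mm: 5.0
  rand_sd_x_mm: 0.049
  rand_sd_y_mm: 0.044
  mu_sd: 2.0e-4
  size_sd_x_mm: 0.131
  size_sd_y_mm: 0.166
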