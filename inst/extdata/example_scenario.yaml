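# Example scenario configuration for the perosense CLI.
# Any key omitted falls back to the package defaults (the reference
# operating point: half-lives 480/30 min at 200 mg/dL, beta = 1.5,
# sigma_S = 0.02, 200 nm film with D_H = 1e-18 m^2/s).
model:
  t_half_base_min: 480
  t_half_ref_min: 30
  G_ref_mgdl: 200
  beta: 1.5
readout:
  sigma_S: 0.02
  t_read_min: 30
  window_max_min: 60
film:
  L_nm: 200
  Nx: 101
  D_H_m2s: 1.0e-18
  k_cons_per_min: 0.02
run:
  t_max_min: 120
  glucose_mgdl: [70, 100, 126, 140, 200, 300]
  seed: 1
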