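# Aerobic batch culture of S. cerevisiae LBG H 1022 on glucose (classic
# diauxic-growth experiment). Setup values marked "reconstructed" resolve
# typographically run-together table cells in the source; V0 is assumed 1 l.
name: lbg_h1022_batch
initial_state:
  G0: 9.0          # g, reconstructed
  P0: 5.0e-05      # g
  E0: 0.1          # g, reconstructed
  C_M0: 0.17       # g, reconstructed
  R0: 0.0
  I0: 0.0
  D0: 0.0
  V0: 1.0          # l, assumed (not tabulated)
time:
  t0: 3.0          # h, reconstructed
  t_END: 21.0      # h
feeding:
  mode: none
lag_enabled: false
volume_mode: consistent
parameters:
  v_G: 3.3
  k_G: 0.2
  eta_G: 0.76
  v_RP: 1.5
  k_RP: 0.24
  eta_RP: 0.80
  v_F: 3.3
  k_F: 0.13
  eta_FE: 0.595
  eta_FP: 0.13
  v_RE: 0.20
  k_RE: 0.12
  eta_RE: 0.65
  v_A: 0.2
  k_A: 0.05
  eta_A: 0.2
  r_max: 0.3
  delta: 0.05
  tau: 0.6
  rho: 0.01
  sigma_I: 1.0
  sigma_E: 1.4
  c: 0.01
  a: 2.0e-04
  b: 30.0
  P_max: 1.0
  E_max: 100.0
  I_max: 1.0
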