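# Extended aerobic fed-batch of the prototroph S. cerevisiae CEN.PK113-7D:
# batch phase on 20 g glucose, then exponentially increasing feeding at
# SFR 0.16 1/h from t = 17 h. V0 = 1 l per the experimental description;
# fields marked "reconstructed" resolve run-together table cells.
name: cenpk113_7d_fedbatch_016
initial_state:
  G0: 20.0         # g, reconstructed
  P0: 5.0e-05      # g
  E0: 0.0          # g, reconstructed
  C_M0: 0.022      # g, reconstructed
  R0: 0.0
  I0: 0.0
  D0: 0.0
  V0: 1.0          # l
time:
  t0: 0.0          # h, reconstructed
  t_END: 49.0      # h
feeding:
  mode: exponential
  t_F: 17.0        # h, reconstructed
  mu: 0.16         # 1/h (SFR)
  c_F: 500.0       # g/l, reconstructed
  M_F: 3.66        # g
  y_R: 0.5
lag_enabled: false
volume_mode: consistent
parameters:
  v_G: 5.8
  k_G: 0.27
  eta_G: 0.86
  v_RP: 1.0
  k_RP: 0.24
  eta_RP: 0.80
  v_F: 2.6
  k_F: 0.14
  eta_FE: 0.60
  eta_FP: 0.20
  v_RE: 0.20
  k_RE: 0.15
  eta_RE: 0.80
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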