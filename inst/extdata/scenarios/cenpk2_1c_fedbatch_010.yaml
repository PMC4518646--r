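# Extended aerobic fed-batch of the auxotroph S. cerevisiae CEN.PK2-1C:
# batch phase on 20 g glucose, then exponentially increasing feeding at SFR 0.10 1/h from t = 15 h.
# V0 = 1 l per the experimental description; fields marked "reconstructed"
# resolve run-together table cells (SFR/t_END/M_F triplets paired
# positionally).
name: cenpk2_1c_fedbatch_010
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
  t_END: 31.0        # h, reconstructed
feeding:
  mode: exponential
  t_F: 15.0        # h, reconstructed
  mu: 0.1          # 1/h (SFR)
  c_F: 500.0       # g/l, reconstructed
  M_F: 4.52        # g, reconstructed
  y_R: 0.5
lag_enabled: false
volume_mode: consistent
parameters:
  v_G: 5.8
  k_G: 0.27
  eta_G: 0.64
  v_RP: 0.83
  k_RP: 0.18
  eta_RP: 0.73
  v_F: 6.57
  k_F: 0.16
  eta_FE: 0.61
  eta_FP: 0.10
  v_RE: 0.11
  k_RE: 0.15
  eta_RE: 0.80
  v_A: 0.3
  k_A: 0.03
  eta_A: 0.2
  r_max: 0.3
  delta: 0.1
  tau: 0.6
  rho: 0.02
  sigma_I: 1.68
  sigma_E: 1.4
  c: 0.01
  a: 2.0e-04
  b: 30.0
  P_max: 1.0
  E_max: 100.0
  I_max: 1.0
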