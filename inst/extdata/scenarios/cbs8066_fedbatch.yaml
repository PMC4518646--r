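# Short aerobic fed-batch of S. cerevisiae CBS 8066: 3 h of exponentially
# increasing feeding at SFR 0.3 1/h, then constant feeding; lag phase on
# glucose uptake enabled. V0 is assumed 1 l (not tabulated); fields marked
# "reconstructed" resolve run-together or internally inconsistent table
# cells in the source:
#   - C_M0: the medium starts glucose-free, so the culture cannot grow
#     before feeding; the tabulated cell mass at feeding start (M_F = 3.66 g)
#     is therefore also the initial cell mass.
#   - y_R: the printed 0.1 makes the initial feed 10x the uptake capacity of
#     a 3.66 g culture and the run then never consumes its ethanol, which
#     contradicts the reported behaviour (ethanol depleted ~8 h, growth at
#     the imposed SFR 0.3); the feed-design yield 0.5 used for the other
#     fed-batch runs restores both and is adopted here.
name: cbs8066_fedbatch
initial_state:
  G0: 0.0          # g, reconstructed
  P0: 5.0e-05      # g
  E0: 0.0          # g, reconstructed
  C_M0: 3.66       # g, reconstructed (= M_F; see header note)
  R0: 0.0
  I0: 0.0
  D0: 0.0
  V0: 1.0          # l, assumed
time:
  t0: 0.0          # h, reconstructed
  t_END: 13.0      # h
feeding:
  mode: two_phase
  t_F: 3.2         # h, reconstructed
  mu: 0.3          # 1/h (SFR)
  t_switch: 3.0    # h of exponential feeding before the constant phase
  c_F: 100.0       # g/l, reconstructed
  M_F: 3.66        # g
  y_R: 0.5         # reconstructed (printed value 0.1; see header note)
lag_enabled: true
volume_mode: consistent
parameters:
  v_G: 5.1
  k_G: 0.2
  eta_G: 0.76
  v_RP: 0.67
  k_RP: 0.21
  eta_RP: 0.80
  v_F: 4.17
  k_F: 0.18
  eta_FE: 0.80
  eta_FP: 0.16
  v_RE: 0.14
  k_RE: 0.12
  eta_RE: 0.55
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
  l1: 0.58
  l2: 2.0e-05
  l3: 5.8
  P_max: 1.0
  E_max: 100.0
  I_max: 1.0
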