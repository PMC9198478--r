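neuron:
  membrane:
    tau_ms: 20.0
    v_rest_mV: -65.0
    R_MOhm: 20.0
    v_threshold_mV: -62.0
    v_reset_mV: -65.0
  groups:
  - E_s_mV: 0
    tau_s_ms: 1.0
    g_max_pS: 100.0
    jump_mode: additive_unbounded
  mapping:
    '1': 1
    '2': 1
    '3': 1
    '4': 1
  drive_scale: 1.0
dt_ms: 0.1
protocol:
  mode: spike
  table: cfbp_m2.csv
  episode_ms: 500.0
  t0_ms: 10.0
  seed: 1
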