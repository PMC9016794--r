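# reduced onset-time sweep at the strong-coupling reference configuration
# (the full reference protocol uses t_c_end: 1030 and dt_c: 0.05 -> 601 runs)
coupling: {v_sw: 2.0, K_ICdk1: 0.5}
sweep:
  t_c_start: 1000
  t_c_end: 1006
  dt_c: 1.0
  post_discard: 720
  post_window: 360
output_dir: onset_sweep_demo_out
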