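# back-and-forth sweep of the saddle-node unfolding parameter mu of the
# radial hysteresis fixture; backward branch started on the outer cycle
model: {name: ring_hysteresis, c_center: 4.0, mu: 0.25}
parameter: mu
lo: -0.5
hi: 1.0
n_steps: 13
settle: 300
y0: {x: 1.0, y: 0.0}
y0_backward: {x: 2.2360680, y: 0.0}
output_dir: hysteresis_demo_out
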