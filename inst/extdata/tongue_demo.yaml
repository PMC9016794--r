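# Arnold-tongue map of the clock forced on its mRNA synthesis rate
model: {name: goodwin_clock}
target: v1
period_grid: [22.0, 23.0, 23.5, 24.5, 25.0, 26.0]
amplitude_grid: [0.0, 0.2, 0.4]
n_phases: 1
y0: {M: 0.1, P: 0.1, I: 0.1}
output_dir: tongue_demo_out
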