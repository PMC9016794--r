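# birhythmic normal-form oscillator started on its inner limit cycle
model:
  name: normal_form
  radii: [1.0, 2.0, 3.0]
y0: {x: 1.0, y: 0.0}
t_end: 300
discard: 150
output_dir: normal_form_demo_out
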