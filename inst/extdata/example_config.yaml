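# Example scenario configuration: WFS1-deficient model under stepwise stress
variant: standard
knockout:
  - wfs1
overrides:
  extCHOP: 0.0
protocol:
  rates: [12, 15, 18]
  durations: 500
analysis:
  t_end: 1500
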