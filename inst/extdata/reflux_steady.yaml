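# Desk-scale reflux-loop steady state: equilibrium profiles through a
# vascular and an epidermal cell file plus the fitted gradient summary.
# Run:  rootflux simulate --config reflux_steady.yaml --out run_reflux
mechanism: reflux_loop
layout:
  segment_length: 1200
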