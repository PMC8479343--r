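# Duration effect at fixed drug totals (123 IFN-beta, 690 cisplatin)
experiment: fig9
schedule:
  h_s_values: [2, 1, 0.5, 0.1]
solver:
  dt_out: 0.01
  dt_max: 0.002
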