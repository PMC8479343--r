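# All 20 orderings of 3 IFN-beta + 3 cisplatin slots at fixed rates
experiment: fig7
solver:
  dt_out: 0.01
  dt_max: 0.002
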