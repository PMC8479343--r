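# IFN-beta half-life sensitivity of the three strategies
experiment: fig11
solver:
  dt_out: 0.02
  dt_max: 0.005
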