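# Optimal IFN-beta profile on fixed injection schemes
experiment: fig12
schedule:
  sequences: [SSSDDD, DSDDSS]
solver:
  dt_out: 0.01
  dt_max: 0.002
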