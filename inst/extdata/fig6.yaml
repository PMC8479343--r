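# Pulsed IFN-beta monotherapy: dose response at t = 25
experiment: fig6
solver:
  dt_out: 0.01
  dt_max: 0.002
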