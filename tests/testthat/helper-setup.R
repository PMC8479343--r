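# shared fixtures: everything is built in code at test time
default_p <- stat_params()
default_th <- stat_thresholds()
default_ic <- default_initial_state(default_p, default_th)

# coarse-but-adequate integrator settings for the slower experiments
fast <- list(dt_out = 0.02, dt_max = 0.005)

sim_fast <- function(...) {
  simulate_model(..., dt_out = fast$dt_out, dt_max = fast$dt_max)
}
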