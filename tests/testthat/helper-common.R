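# Shared fixtures, built in code.

# A course of vertical (90 degree) segments: the line is the constant
# x = `x` for its whole extent.
straight_course <- function(n_segments = 22, x = 150) {
  generate_course(n_segments, x_bounds = c(x - 1, x + 1), start_x = x,
                  angles = 90)
}

# Toy configuration for oracle comparisons: every interval an integer
# number of milliseconds (50 Hz command channel), short trials.
toy_env <- function(...) {
  env_config(..., command_rate = 50, trial_duration = 2)
}
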