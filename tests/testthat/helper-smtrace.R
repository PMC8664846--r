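# Shared fixtures, built in code at test time.

unit178 <- list(mean = 178.2, sd = 58.6)

# Piecewise-constant staircase trace with optional iid Gaussian noise.
staircase_trace <- function(levels, lens, sd = 0, dt = 0.1) {
  y <- rep(levels, lens)
  if (sd > 0) y <- y + rnorm(length(y), 0, sd)
  sm_trace(y, dt)
}

# Build an ideal_trace directly from segment bounds/levels (for classifier
# rule tests where the segmentation itself is the given).
make_ideal <- function(levels, lens, dt) {
  tr <- staircase_trace(levels, lens, sd = 0, dt = dt)
  idealize_trace(tr, max_states = length(levels))
}

# Random-seeded small config helpers
quick_cal_cfg <- function(seed, n_frames = 400, ...) {
  sim_config("CALIBRATION", seed = seed, n_frames = n_frames, ...)
}
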