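# shared fixtures: all randomness in tests goes through explicit seeds

# a deterministic, well-linearised sensor (no noise of any kind)
quiet_config <- function(...) {
  sensor_config(dark_sd = 0, read_noise_sd = 0, shot_noise = FALSE, ...)
}

# published coefficients recommended for otherwise uncalibrated units
unit_c_model <- function() lin_model(0.14231, 1.06125)

# a second simulated unit whose response differs from unit C by a
# realistic between-unit spread
unit_e_model <- function() lin_model(0.18, 1.08)

# noiseless exposure ramp generated by inverting the linearisation
# response: the generative oracle for fit recovery
oracle_ramp <- function(model, octaves = 10, scale = 5e4) {
  t_ms <- 2^(0:octaves)
  r <- t_ms / max(t_ms)
  data.frame(integration_ms = t_ms,
             summed_counts = scale * lin_invert(r, model),
             saturated = FALSE)
}
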