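# Small shared fixtures, built in code at test time.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(width = 48L, height = 40L, n_frames = 4L,
                   n_particles = 2L, particle_radius = c(2.5, 3.5),
                   seed = 11L)
  do.call(sim_config, c(args, defaults[!names(defaults) %in% names(args)]))
}

# A wave-bearing reference stream for tile tests.
wave_reference <- function(seed = 5L, width = 64L, height = 64L,
                           n_frames = 6L) {
  simulate_reference_stream(sim_config(
    width = width, height = height, n_frames = n_frames,
    artifacts = wave_intervals(gamma_range = c(0.1, 0.25)), seed = seed))
}

# Deterministic wave parameter set with a single wave.
one_wave <- function(c_w = c(10, 10), c_f = c(10, 10), sigma = 0.3,
                     omega = 0, beta = 1, gamma = 0.2) {
  wave_params(centers = matrix(c_w, 1), fade_centers = matrix(c_f, 1),
              sigma = sigma, omega = omega, beta = beta, gamma = gamma)
}
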