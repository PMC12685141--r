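# Shared fixture builders; everything is generated in code.

fine_spec <- function(snr = Inf, seed = 1L, shape = c(96L, 96L), ...) {
  scene_spec(pixel_size = 1, shape = shape, monomer_radius = 13.2,
             snr = snr, seed = seed, ...)
}

centered_monomer <- function(spec = fine_spec()) {
  particle_truth(1L, "monomer", (spec$shape[1:2] - 1) / 2 * spec$pixel_size)
}

centered_dimer <- function(separation, theta = 0, spec = fine_spec()) {
  particle_truth(1L, "dimer", (spec$shape[1:2] - 1) / 2 * spec$pixel_size,
                 axis = c(cos(theta), sin(theta), 0), separation = separation)
}

benchmark_spec <- function(seed) {
  scene_spec(pixel_size = 10, shape = c(96L, 96L, 96L), n_particles = 75L,
             monomer_fraction = 50 / 75, dimer_fraction = 25 / 75,
             dimer_separation_mean = 40, dimer_separation_sd = 0,
             snr = 5, seed = seed, min_center_distance = 60,
             tilt_range = c(-48, 48))
}

q_default <- seq(0.01, 0.5, by = 0.002)
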