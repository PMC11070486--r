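## Shared fixture builders (all generated in code; nothing stored on disk).

linear_truth <- function(h0 = 3.7, E0 = 60, noise_scale = 0, ...) {
  tissue_ground_truth("lin", h0 = h0, toe_modulus = E0,
                      stiffening_rate = 0, relax_time = 0,
                      noise_scale = noise_scale, ...)
}

jshape_truth <- function(h0 = 3.7, E0 = 40, gamma = 4, ...) {
  tissue_ground_truth("jay", h0 = h0, toe_modulus = E0,
                      stiffening_rate = gamma, relax_time = 0,
                      noise_scale = 0, ...)
}

## hand-built single-frame recording with Gaussian-modulated pulses at
## given depths; bypasses the package's renderer
toy_recording <- function(centers_mm, n_frames = 1,
                          cfg = acquisition_config(),
                          amp_scale = 1, depth_max = 20) {
  dz <- cfg$sound_speed / (2 * cfg$rf_sampling * 1e6) * 1e3
  sz <- cfg$sound_speed * cfg$pulse_sigma * 1e-6 / 2 * 1e3
  period <- cfg$sound_speed / (2 * cfg$carrier_mhz * 1e6) * 1e3
  depth <- seq(0, depth_max, by = dz)
  one <- rowSums(sapply(centers_mm, function(z0)
    exp(-(depth - z0)^2 / (2 * sz^2)) * cos(2 * pi * (depth - z0) / period)))
  amp <- matrix(rep(one, n_frames), ncol = n_frames) * amp_scale
  list(frames = list(times = seq_len(n_frames) - 1, depth_mm = depth,
                     amplitude = amp),
       force = list(times = seq_len(n_frames) - 1,
                    force_N = rep(1, n_frames)),
       protocol = loading_protocol(), config = cfg,
       overlap_flagged = FALSE)
}
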