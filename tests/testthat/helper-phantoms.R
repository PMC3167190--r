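# Shared phantom configurations. 48^3 grids keep the suite fast while
# leaving a WM core big enough (semi-axis ~16 voxels) for multi-lesion
# layouts; acceptance-facing checks use the 64^3 default grid.

two_lesions <- function(factor = 1.8, shape = 48) {
  ctr <- (shape + 1) / 2
  # centres 11.2 voxels apart: both spheres stay inside the WM core
  # (radius ~0.34 * shape) and never touch, even diagonally
  list(lesion_spec(c(ctr, ctr, ctr), 5, factor),
       lesion_spec(c(ctr - 9, ctr - 6, ctr - 3), 3, factor))
}

ph_noise_free <- function(factor = 1.8, shape = 48, seed = 7) {
  generate_phantom(phantom_spec(shape = rep(shape, 3),
                                lesions = two_lesions(factor, shape),
                                noise_sd = 0, seed = seed))
}

ph_noisy <- function(factor = 1.8, noise_sd = 10, shape = 48, seed = 7,
                     n_flow = 0, flow_factor = NULL) {
  ints <- list(background = 0, csf = 30, gm = 110, wm = 100,
               flow_factor = if (is.null(flow_factor)) max(2, factor) else flow_factor)
  generate_phantom(phantom_spec(shape = rep(shape, 3),
                                lesions = two_lesions(factor, shape),
                                intensities = ints,
                                noise_sd = noise_sd, n_flow_voxels = n_flow,
                                seed = seed))
}

# Bright, well-defined lesions (~mean + 5 SD of the in-brain histogram)
# that both segmenters should recover.
ph_bright <- function(noise_sd = 5, shape = 48, seed = 7, n_flow = 0) {
  ints <- list(background = 0, csf = 30, gm = 110, wm = 100, flow_factor = 2.8)
  generate_phantom(phantom_spec(shape = rep(shape, 3),
                                lesions = two_lesions(2.6, shape),
                                intensities = ints,
                                noise_sd = noise_sd, n_flow_voxels = n_flow,
                                seed = seed))
}
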