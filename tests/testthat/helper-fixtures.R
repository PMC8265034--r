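# Shared fixtures: small phantoms and training cases built in code.

tiny_phantom_config <- function(shape = c(64L, 64L, 4L),
                                lesion_radius_vox = c(2, 5), ...) {
  phantom_config(shape = shape, lesion_radius_vox = lesion_radius_vox, ...)
}

tiny_phantom <- function(seed = 1L, ...) {
  generate_phantom(tiny_phantom_config(...), seed = seed)
}

# a coarse dictionary that is fast to search in unit tests
coarse_grid <- function() {
  parameter_grid(rel_step = 0.25)
}

tiny_training_config <- function(epochs = 2L, base_channels = 4L, ...) {
  training_config(patch_size = 16L, patches_per_slice = 4L, batch_size = 4L,
                  epochs = epochs, base_channels = base_channels,
                  encoder_depth = 2L, learning_rate = 1e-3, ...)
}

# phantom -> noisy stack -> training case with ground-truth targets
tiny_case <- function(seed = 1L, config = tiny_training_config(),
                      snr = 40, pconfig = tiny_phantom_config()) {
  ph <- generate_phantom(pconfig, seed = seed)
  st <- add_rician_noise(simulate_baseline_stack(ph), snr = snr,
                         seed = seed + 1000L)
  list(case = make_training_case(st, list(
         t1_ms = ph$t1_map, t2s_ms = ph$t2s_map,
         prob_nawm = ph$prob_nawm, prob_gm = ph$prob_gm,
         lesion_mask = ph$lesion_mask), config),
       phantom = ph, stack = st)
}
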