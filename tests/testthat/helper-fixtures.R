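# Shared fixtures: small phantoms and tiny network configurations, built in
# code so tests carry no data files. Heavier objects are cached per session.

small_cfg <- function(seed = 1L, noise_sd = 0.02, bias_field_amplitude = 0.1,
                      lesion_probability = 0.6, ...) {
  phantom_config(grid_shape = c(32L, 32L, 20L), n_null_slices = c(3L, 3L),
                 noise_sd = noise_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 lesion_probability = lesion_probability, seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- make()
  .fixture_env[[key]]
}

small_subject <- function(seed = 1L) {
  cached(paste0("subj", seed),
         function() generate_paired_subject(small_cfg(seed)))
}

tiny_unet <- function(size = 16L, depth = 2L, filters = 2L, dropout = NULL) {
  build_layer_graph(unet_config(input_shape = c(size, size, 1L),
                                depth = depth, base_filters = filters,
                                dropout_schedule = dropout))
}

# A volume wrapper for hand-built arrays.
as_cvol <- function(x, contrast = "T1", id = "manual") {
  structure(list(subject_id = id, contrast_name = contrast,
                 intensities = x, voxel_size_mm = 1),
            class = "contrast_volume")
}
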