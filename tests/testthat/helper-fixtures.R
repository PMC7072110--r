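# Shared fixtures: tiny network configs and in-code phantom pools.

tiny_net_config <- function(seed = 1L, input = 64L, base = 4L) {
  unet_config(depth = 2L, base_filters = base, input_size = c(input, input),
              seed = seed, learning_rate = 5e-3, batch_size = 1L)
}

micro_net_config <- function(seed = 1L) {
  unet_config(depth = 2L, base_filters = 2L, input_size = c(32L, 32L),
              seed = seed, learning_rate = 5e-3, batch_size = 2L)
}

jitterfree_config <- function(shape = c(64L, 64L)) {
  variation_config(shape = shape, geometry_jitter = 0, noise_sd = c(0, 0),
                   artifact_count = c(0L, 0L), brightness = c(0, 0),
                   contrast = c(1, 1))
}

as_training_pool <- function(records) {
  lapply(records, function(r) {
    list(id = r$id, image = standardize(r$image), mask = r$mask)
  })
}

# Committee whose "members" return fixed feature vectors, for testing the
# disagreement machinery without trained networks.
stub_committee <- function(vectors) {
  structure(list(members = lapply(vectors, function(v) function(image) v)),
            class = "committee")
}

random_binary_mask <- function(h, w, p = 0.5) {
  matrix(as.numeric(stats::runif(h * w) < p), h, w)
}
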