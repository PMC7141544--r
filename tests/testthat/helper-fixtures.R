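# Shared fixtures: everything is generated in code at test time.

# A small phantom scene used across tests.
small_phantom_config <- function(noise_sd = 0.02, ...) {
  phantom_config(height = 64L, width = 64L, thorax_extent = 52L,
                 heart_extent = 22L, noise_sd = noise_sd, ...)
}

# A desk-scale network spec (widths 2-4-8-16) that keeps forward and
# backward passes fast in unit tests.
tiny_spec <- function(num_classes = 4L, input_channels = 1L) {
  make_spec(width_multiplier = 0.03125, num_classes = num_classes,
            input_channels = input_channels)
}

random_mask <- function(h, w, num_classes = 4L, seed = 1L) {
  cxrmesh:::with_seed(seed,
    matrix(sample(0:(num_classes - 1L), h * w, replace = TRUE), h, w))
}

# Mean foreground Jaccard of a segmenter over a sample list.
mean_foreground_jaccard <- function(net, samples, num_classes = 4L) {
  js <- vapply(samples, function(s) {
    pred <- segment_image(net, s$image)
    score(confusion(pred, s$mask, num_classes))$mean_j
  }, numeric(1))
  mean(js)
}
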