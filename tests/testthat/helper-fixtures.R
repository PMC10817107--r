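# Shared fixtures, built in code. Kept deliberately small: most tests
# work at reduced sampling rates / epoch counts so the suite stays fast.

# Band power fraction from an independent periodogram (stats::spec.pgram),
# used as the oracle for the synthetic generator's spectral claims.
oracle_band_fraction <- function(x, fs, f_lo, f_hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = FALSE, plot = FALSE)
  band <- sp$freq >= f_lo & sp$freq <= f_hi
  sum(sp$spec[band]) / sum(sp$spec)
}

# A small cached image dataset for model tests (built once per test run).
small_image_set <- local({
  cache <- NULL
  function(n_per_class = 6, seed = 11) {
    if (is.null(cache)) {
      ds <- generate_dataset(n_per_class, fs = 200, seed = seed)
      cache <<- epochs_to_images(ds)
    }
    cache
  }
})

# Low-capacity variant with the standard 64x64x3 input, for fast
# training-loop tests on real scalogram images.
tiny64_spec <- function() {
  cnn_spec(list(
    layer_input(c(64, 64, 3)),
    layer_conv(8, 3),
    layer_batch_norm(8),
    layer_relu(),
    layer_max_pool(3, 2),
    layer_conv(8, 3),
    layer_batch_norm(8),
    layer_relu(),
    layer_max_pool(3, 2),
    layer_fully_connected(5),
    layer_softmax(),
    layer_classification()
  ))
}

# Tiny architecture that exercises every layer kind but runs in
# milliseconds; used for gradient and engine tests.
tiny_spec <- function(units = 5) {
  cnn_spec(list(
    layer_input(c(8, 8, 2)),
    layer_conv(4, 3),
    layer_batch_norm(4),
    layer_relu(),
    layer_max_pool(2, 2),
    layer_conv(3, 3),
    layer_batch_norm(3),
    layer_relu(),
    layer_fully_connected(units),
    layer_softmax(),
    layer_classification()
  ))
}
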