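#' Run the full sleep-staging pipeline on synthetic EEG
#'
#' End-to-end surrogate for the reference experiment at desk scale:
#' synthesize labeled multi-channel-style EEG (one channel), apply the
#' notch + bandpass preprocessing chain, segment into 30-s epochs,
#' transform each epoch to a bump-wavelet scalogram image, split
#' stratified 70/15/15, train the 19-layer CNN with Adam, and evaluate on
#' the held-out test split.
#'
#' @param n_per_class Epochs synthesized per sleep stage (default 200).
#' @param fs Sampling rate in Hz (default 200).
#' @param spec A [stage_spectrum_spec()].
#' @param seed Integer master seed; every stochastic stage (synthesis,
#'   split, weight init, shuffling) is derived from it.
#' @param channel Montage label to synthesize (default `"C4-A1"`).
#' @param cfg A [train_config()]. The default here caps training at 20
#'   epochs with early stopping at 0.995 validation accuracy, sized for a
#'   single-CPU run; the optimizer settings themselves (Adam, lr 0.001,
#'   batch 128) are the reference configuration.
#' @param grid Optional [build_scale_grid()]; defaults to 0.5-32 Hz, 12
#'   voices per octave.
#' @param wavelet A [bump_wavelet()].
#' @param split A [split_spec()]; defaults to stratified 70/15/15.
#' @param verbose Print progress lines.
#' @return A `sleep_pipeline_result`: list with the trained `model`,
#'   `metrics` (a `stage_metrics` for the test split), `auc`, `confusion`,
#'   `splits` (row counts), `history`, and the test-set predictions.
#' @export
run_sleep_pipeline <- function(n_per_class = 200, fs = 200,
                               spec = stage_spectrum_spec(), seed = 1L,
                               channel = "C4-A1",
                               cfg = train_config(max_epochs = 20,
                                                  early_stop_val_acc = 0.995,
                                                  seed = seed),
                               grid = NULL, wavelet = bump_wavelet(),
                               split = split_spec(seed = seed),
                               verbose = FALSE) {
  seed <- as.integer(seed)
  say <- function(...) if (verbose) message(sprintf(...))

  say("synthesizing %d epochs/class at %g Hz", n_per_class, fs)
  set.seed(seed)
  stage_seq <- sample(rep(stage_levels(), each = n_per_class))
  # several moderate recordings rather than one huge one
  chunk <- 50L
  epochs_list <- list()
  starts <- seq(1L, length(stage_seq), by = chunk)
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:min(length(stage_seq), starts[ci] + chunk - 1L)
    rec <- generate_recording(stage_seq[idx], fs = fs, spec = spec,
                              seed = seed + ci, channels = channel)
    rec <- apply_filters(rec, default_filter_chain(fs))
    seg <- segment_epochs(rec)
    seg$epoch <- seg$epoch + idx[1] - 1L
    epochs_list[[ci]] <- seg
  }
  epochs <- dplyr::bind_rows(epochs_list)

  say("rendering %d scalogram images", nrow(epochs))
  if (is.null(grid)) grid <- build_scale_grid(fs = fs, wavelet = wavelet)
  images <- epochs_to_images(epochs, grid = grid, wavelet = wavelet)

  parts <- split_dataset(images, split)
  say("split: train %d / val %d / test %d", nrow(parts$train),
      nrow(parts$val), nrow(parts$test))

  model <- build_model(default_model_spec(), seed = seed)
  model <- train_cnn(model, parts$train, parts$val, cfg, verbose = verbose)

  proba <- predict_proba(model, parts$test)
  pred <- factor(model$classes[max.col(proba, ties.method = "first")],
                 levels = model$classes)
  cm <- confusion(parts$test$stage, pred)
  metrics <- metrics_from_confusion(cm)
  auc <- auc_ovr(parts$test$stage, proba)
  say("test: overall accuracy %.4f, macro F1 %.4f",
      attr(metrics, "overall_accuracy"), attr(metrics, "macro")[["f1"]])

  structure(
    list(model = model, metrics = metrics, auc = auc, confusion = cm,
         history = model$history,
         splits = c(train = nrow(parts$train), val = nrow(parts$val),
                    test = nrow(parts$test)),
         test_truth = stage_factor(parts$test$stage),
         test_pred = pred, test_proba = proba,
         seed = seed, n_per_class = n_per_class, channel = channel),
    class = "sleep_pipeline_result"
  )
}

#' @export
print.sleep_pipeline_result <- function(x, ...) {
  cat(sprintf("<sleep_pipeline_result> channel %s, %d epochs/class, seed %d\n",
              x$channel, x$n_per_class, x$seed))
  cat(sprintf("  split: %d / %d / %d (train/val/test)\n",
              x$splits["train"], x$splits["val"], x$splits["test"]))
  cat(sprintf("  test overall accuracy: %.4f\n",
              attr(x$metrics, "overall_accuracy")))
  cat(sprintf("  test macro F1:         %.4f\n",
              attr(x$metrics, "macro")[["f1"]]))
  cat(sprintf("  test macro AUC:        %.4f\n", x$auc$macro))
  invisible(x)
}
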