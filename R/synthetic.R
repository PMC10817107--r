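#' Stage-dependent spectral recipe for synthetic EEG
#'
#' Describes, per sleep stage, the narrowband oscillations that dominate a
#' 30-s epoch of scalp EEG, plus broadband noise and 50 Hz mains
#' interference. The defaults mirror textbook AASM band structure:
#' wake is alpha/beta dominated, N1 theta, N2 theta with 1-s sigma-band
#' spindle bursts, N3 high-amplitude delta, and REM mixed low-amplitude
#' theta/beta. Amplitudes are relative (the generator's unit is arbitrary,
#' think tens of microvolts).
#'
#' @param components Named list (one entry per stage in [stage_levels()]),
#'   each a data frame with columns `center_hz`, `bandwidth_hz`,
#'   `amplitude` and logical `burst` (TRUE renders the component as 1-s
#'   bursts rather than a sustained oscillation, as sleep spindles are).
#' @param noise_sd Standard deviation of additive Gaussian noise, in signal
#'   units. Default 0.3.
#' @param line_hz Powerline frequency in Hz. Default 50.
#' @param line_amplitude Amplitude of the mains interference sinusoid, in
#'   signal units. Default 0.2, large enough that an unfiltered scalogram
#'   would show it, so the notch stage is genuinely exercised.
#' @return An object of class `stage_spectrum_spec`.
#' @export
#' @examples
#' spec <- stage_spectrum_spec()
#' spec$components$N3
stage_spectrum_spec <- function(components = NULL,
                                noise_sd = 0.3,
                                line_hz = 50,
                                line_amplitude = 0.2) {
  comp <- function(f, bw, a, burst = FALSE) {
    data.frame(center_hz = f, bandwidth_hz = bw, amplitude = a, burst = burst)
  }
  if (is.null(components)) {
    components <- list(
      W   = rbind(comp(10, 1.0, 1.0), comp(20, 2.0, 0.5)),
      N1  = comp(5, 1.0, 1.0),
      N2  = rbind(comp(5, 1.0, 0.8), comp(13, 1.0, 1.0, burst = TRUE)),
      N3  = comp(1, 0.5, 2.0),
      REM = rbind(comp(6, 1.0, 0.6), comp(22, 2.0, 0.4))
    )
  }
  stopifnot(setequal(names(components), stage_levels()))
  for (st in names(components)) {
    cmp <- components[[st]]
    if (any(cmp$center_hz <= 0) || any(cmp$amplitude < 0)) {
      stop("invalid component for stage ", st,
           ": center frequencies must be positive and amplitudes >= 0",
           call. = FALSE)
    }
  }
  if (noise_sd < 0 || line_amplitude < 0) {
    stop("noise_sd and line_amplitude must be >= 0", call. = FALSE)
  }
  structure(
    list(components = components[stage_levels()], noise_sd = noise_sd,
         line_hz = line_hz, line_amplitude = line_amplitude),
    class = "stage_spectrum_spec"
  )
}

# One synthetic epoch for a given stage. Random draws (component frequency,
# phases, burst onsets, noise) come from the current RNG stream, so callers
# control reproducibility with set.seed().
synth_epoch_signal <- function(stage, fs, epoch_seconds, spec) {
  n <- as.integer(round(epoch_seconds * fs))
  t <- seq(0, by = 1 / fs, length.out = n)
  x <- numeric(n)
  cmp <- spec$components[[as.character(stage)]]
  for (i in seq_len(nrow(cmp))) {
    f <- cmp$center_hz[i]
    if (cmp$bandwidth_hz[i] > 0) {
      f <- f + stats::runif(1, -0.5, 0.5) * cmp$bandwidth_hz[i]
    }
    if (f >= fs / 2) {
      stop("component frequency ", f, " Hz is not below the Nyquist limit ",
           fs / 2, " Hz", call. = FALSE)
    }
    phase <- stats::runif(1, 0, 2 * pi)
    tone <- cmp$amplitude[i] * sin(2 * pi * f * t + phase)
    if (isTRUE(cmp$burst[i])) {
      tone <- tone * burst_envelope(n, fs)
    }
    x <- x + tone
  }
  if (spec$line_amplitude > 0) {
    x <- x + spec$line_amplitude *
      sin(2 * pi * spec$line_hz * t + stats::runif(1, 0, 2 * pi))
  }
  if (spec$noise_sd > 0) x <- x + stats::rnorm(n, sd = spec$noise_sd)
  x
}

# 1-s bursts recurring every `period` seconds, onset jittered per epoch,
# with 0.1-s raised-cosine edges to limit spectral splatter.
burst_envelope <- function(n, fs, burst_seconds = 1, period = 6) {
  env <- numeric(n)
  offset <- stats::runif(1, 0, period)
  starts <- seq(offset, n / fs, by = period)
  ramp <- max(1L, as.integer(round(0.1 * fs)))
  core <- as.integer(round(burst_seconds * fs))
  shape <- c(0.5 * (1 - cos(pi * seq_len(ramp) / ramp)),
             rep(1, max(0L, core - 2L * ramp)),
             0.5 * (1 + cos(pi * seq_len(ramp) / ramp)))
  for (s in starts) {
    i0 <- as.integer(round(s * fs)) + 1L
    idx <- i0:min(n, i0 + length(shape) - 1L)
    if (idx[1] > n) next
    env[idx] <- pmax(env[idx], shape[seq_along(idx)])
  }
  env
}

#' Generate a labeled multi-channel synthetic EEG recording
#'
#' Builds a recording of consecutive 30-s epochs whose spectral content
#' follows `stage_sequence` under the recipe in `spec`. Channels share the
#' stage sequence (as real polysomnography channels do) but have
#' independent phases, frequency jitter and noise.
#'
#' @param stage_sequence Character vector (or factor) of stage tokens, one
#'   per 30-s epoch.
#' @param fs Sampling rate in Hz. Default 200, the polysomnography rate the
#'   pipeline is designed around.
#' @param spec A [stage_spectrum_spec()].
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @param channels Character vector of montage labels. Defaults to the six
#'   standard ear-referenced channels.
#' @param epoch_seconds Epoch length in seconds (default 30).
#' @return An `eeg_recording`: list with `samples` (channels x time
#'   matrix), `fs`, `channel_names`, `epoch_labels` (factor) and
#'   `epoch_seconds`.
#' @export
#' @examples
#' rec <- generate_recording(c("W", "N3"), fs = 100, seed = 1,
#'                           channels = "C4-A1")
#' dim(rec$samples)
generate_recording <- function(stage_sequence,
                               fs = 200,
                               spec = stage_spectrum_spec(),
                               seed = 1L,
                               channels = c("C3-A2", "C4-A1", "F3-A2",
                                            "F4-A1", "O1-A2", "O2-A1"),
                               epoch_seconds = 30) {
  if (length(stage_sequence) == 0) {
    stop("stage_sequence must be non-empty", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  stages <- stage_factor(stage_sequence)
  n_epoch <- as.integer(round(epoch_seconds * fs))
  set.seed(as.integer(seed))
  samples <- matrix(0, nrow = length(channels),
                    ncol = n_epoch * length(stages))
  for (ch in seq_along(channels)) {
    for (e in seq_along(stages)) {
      idx <- ((e - 1L) * n_epoch + 1L):(e * n_epoch)
      samples[ch, idx] <- synth_epoch_signal(stages[e], fs, epoch_seconds, spec)
    }
  }
  rownames(samples) <- channels
  new_eeg_recording(samples, fs, channels, stages, epoch_seconds)
}

new_eeg_recording <- function(samples, fs, channel_names,
                              epoch_labels = NULL, epoch_seconds = 30) {
  structure(
    list(samples = samples, fs = fs, channel_names = channel_names,
         epoch_labels = epoch_labels, epoch_seconds = epoch_seconds),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (!is.null(x$epoch_labels)) {
    cat("  epochs:  ", length(x$epoch_labels), "labeled,",
        x$epoch_seconds, "s each\n")
  }
  invisible(x)
}

#' Generate a balanced labeled epoch dataset
#'
#' Convenience wrapper that synthesizes `5 * n_per_class` single-channel
#' 30-s epochs (class-balanced, order shuffled) and returns them as a
#' tibble ready for the downstream scalogram/classifier stages.
#'
#' @inheritParams generate_recording
#' @param n_per_class Number of epochs per sleep stage (>= 1).
#' @param channel Montage label used for all epochs (default `"C4-A1"`,
#'   the best-performing channel in the methodology this package
#'   implements).
#' @return Tibble with columns `epoch` (0-based index), `channel`, `stage`
#'   (factor), `fs`, and list-column `signal`.
#' @export
#' @examples
#' ds <- generate_dataset(2, fs = 100, seed = 1)
#' table(ds$stage)
generate_dataset <- function(n_per_class,
                             fs = 200,
                             spec = stage_spectrum_spec(),
                             seed = 1L,
                             channel = "C4-A1",
                             epoch_seconds = 30) {
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    stop("n_per_class must be >= 1", call. = FALSE)
  }
  n_per_class <- as.integer(n_per_class)
  set.seed(as.integer(seed))
  seq_stages <- sample(rep(stage_levels(), each = n_per_class))
  rec <- generate_recording(seq_stages, fs = fs, spec = spec,
                            seed = sample.int(.Machine$integer.max, 1),
                            channels = channel,
                            epoch_seconds = epoch_seconds)
  segment_epochs(rec, epoch_seconds = epoch_seconds)
}
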