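#' Design the powerline notch filter
#'
#' Second-order IIR notch with its numerator zeros exactly on the unit
#' circle at `f0`, so the magnitude response is identically zero at the
#' notch frequency and near-unity elsewhere. The bandwidth is set by the
#' quality factor `q` (-3 dB width approximately `f0 / q`).
#'
#' @param f0 Notch frequency in Hz (default 50, the European powerline).
#' @param fs Sampling rate in Hz.
#' @param q Quality factor (dimensionless). Default 35, i.e. about 1.4 Hz
#'   -3 dB width at 50 Hz, narrow enough to leave the 30 Hz passband edge
#'   untouched.
#' @return A `filter_spec` with transfer-function coefficients `b`, `a`.
#' @export
#' @examples
#' spec <- design_notch(50, fs = 200)
#' abs(filter_response(spec, 50))   # ~0
#' abs(filter_response(spec, 10))   # ~1
design_notch <- function(f0 = 50, fs = 200, q = 35) {
  check_scalar_pos(fs, "fs")
  if (!is.numeric(f0) || f0 <= 0 || f0 >= fs / 2) {
    stop("f0 must lie strictly between 0 and fs/2 = ", fs / 2, " Hz",
         call. = FALSE)
  }
  if (q <= 0) stop("q must be positive", call. = FALSE)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  new_filter_spec("notch", b, a, fs,
                  f_notch = f0, quality = q)
}

#' Design the Butterworth bandpass filter
#'
#' Butterworth bandpass via the bilinear transform (through
#' [signal::butter()]), maximally flat in the passband with single-pass
#' magnitude exactly 1/sqrt(2) (-3.01 dB) at both band edges. `order` is
#' the analog prototype order before the bandpass transformation (an
#' order-2 design yields a 4th-order transfer function), the conventional
#' reading of a "2nd order bandpass Butterworth".
#'
#' @param order Prototype order (>= 1). Default 2.
#' @param f_low,f_high Band edges in Hz. Defaults 0.3 and 30, the standard
#'   sleep-EEG band.
#' @param fs Sampling rate in Hz.
#' @return A `filter_spec`.
#' @export
#' @examples
#' spec <- design_bandpass(2, 0.3, 30, fs = 200)
#' abs(filter_response(spec, 30)) # ~0.7071
design_bandpass <- function(order = 2, f_low = 0.3, f_high = 30, fs = 200) {
  check_scalar_pos(fs, "fs")
  if (!(order >= 1)) stop("order must be >= 1", call. = FALSE)
  if (!(f_low > 0 && f_low < f_high && f_high < fs / 2)) {
    stop("band edges must satisfy 0 < f_low < f_high < fs/2 = ", fs / 2,
         call. = FALSE)
  }
  bt <- signal::butter(order, c(f_low, f_high) / (fs / 2), type = "pass")
  new_filter_spec("butter_bandpass", bt$b, bt$a, fs,
                  order = order, f_low = f_low, f_high = f_high)
}

new_filter_spec <- function(kind, b, a, fs, ...) {
  spec <- structure(
    c(list(kind = kind, b = as.numeric(b), a = as.numeric(a), fs = fs),
      list(...)),
    class = "filter_spec"
  )
  poles <- polyroot(rev(spec$a))
  if (any(Mod(poles) >= 1)) {
    stop("designed filter is unstable (pole on or outside the unit circle)",
         call. = FALSE)
  }
  spec
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s @ fs = %g Hz, order %d\n",
              x$kind, x$fs, length(x$a) - 1L))
  invisible(x)
}

#' Complex frequency response of a designed filter
#'
#' Evaluates the rational transfer function H(z) on the unit circle at the
#' requested physical frequencies (single-pass response; a zero-phase
#' forward-backward application squares the magnitude).
#'
#' @param spec A `filter_spec`.
#' @param f Numeric vector of frequencies in Hz.
#' @return Complex vector `H(f)`.
#' @export
filter_response <- function(spec, f) {
  stopifnot(inherits(spec, "filter_spec"))
  z <- exp(-1i * 2 * pi * f / spec$fs)
  num <- outer(z, seq_along(spec$b) - 1, `^`) %*% spec$b
  den <- outer(z, seq_along(spec$a) - 1, `^`) %*% spec$a
  as.vector(num / den)
}

#' Default preprocessing chain
#'
#' The two-stage chain applied before time-frequency analysis: a 50 Hz
#' powerline notch followed by a 2nd-order Butterworth bandpass with 0.3
#' and 30 Hz cutoffs.
#'
#' @param fs Sampling rate in Hz.
#' @param notch_hz,notch_q Notch frequency and quality factor.
#' @param bp_order,bp_low_hz,bp_high_hz Bandpass prototype order and edges.
#' @return List of two `filter_spec`s, notch first.
#' @export
default_filter_chain <- function(fs = 200, notch_hz = 50, notch_q = 35,
                                 bp_order = 2, bp_low_hz = 0.3,
                                 bp_high_hz = 30) {
  list(design_notch(notch_hz, fs, notch_q),
       design_bandpass(bp_order, bp_low_hz, bp_high_hz, fs))
}

#' Apply a filter chain to a recording
#'
#' Filters every channel independently with each filter in order. By
#' default filters are applied zero-phase (forward-backward,
#' [signal::filtfilt()]) so scalogram morphology is not phase-distorted;
#' note the effective magnitude response is then squared, turning the -3 dB
#' single-pass edges into -6 dB. Set `zero_phase = FALSE` for single-pass
#' causal filtering.
#'
#' @param rec An `eeg_recording`.
#' @param chain List of `filter_spec`s sharing the recording's sampling
#'   rate (default [default_filter_chain()]).
#' @param zero_phase Logical, default TRUE.
#' @return A filtered `eeg_recording` of identical dimensions.
#' @export
apply_filters <- function(rec, chain = default_filter_chain(rec$fs),
                          zero_phase = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (inherits(chain, "filter_spec")) chain <- list(chain)
  for (spec in chain) {
    if (!isTRUE(all.equal(spec$fs, rec$fs))) {
      stop("filter designed for fs = ", spec$fs,
           " Hz cannot be applied to a recording sampled at ", rec$fs, " Hz",
           call. = FALSE)
    }
  }
  out <- rec$samples
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    for (spec in chain) {
      x <- if (zero_phase) {
        signal::filtfilt(spec$b, spec$a, x)
      } else {
        as.numeric(signal::filter(spec$b, spec$a, x))
      }
    }
    out[ch, ] <- x
  }
  new_eeg_recording(out, rec$fs, rec$channel_names, rec$epoch_labels,
                    rec$epoch_seconds)
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts each channel into consecutive non-overlapping windows of
#' `epoch_seconds` (half-open in samples, `[i*L, (i+1)*L)`, 0-based index
#' `i`). Trailing samples shorter than one epoch are discarded. Stage
#' labels attached to the recording are assigned positionally.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_seconds Epoch length in seconds; `epoch_seconds * fs` must
#'   be a whole number of samples. Default 30, the AASM scoring epoch.
#' @return Tibble with columns `epoch` (0-based), `channel`, `stage`
#'   (factor, `NA` if the recording is unlabeled), `fs` and list-column
#'   `signal`.
#' @export
segment_epochs <- function(rec, epoch_seconds = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- epoch_seconds * rec$fs
  if (abs(len - round(len)) > 1e-9) {
    stop("epoch_seconds * fs = ", len, " is not an integer sample count",
         call. = FALSE)
  }
  len <- as.integer(round(len))
  n_ep <- ncol(rec$samples) %/% len
  if (n_ep == 0) {
    return(tibble::tibble(epoch = integer(), channel = character(),
                          stage = stage_factor(character()), fs = numeric(),
                          signal = list()))
  }
  labels <- rec$epoch_labels
  if (!is.null(labels) && length(labels) < n_ep) {
    stop("recording carries ", length(labels), " labels but segments into ",
         n_ep, " epochs", call. = FALSE)
  }
  grid <- expand.grid(epoch = seq_len(n_ep) - 1L,
                      ch = seq_along(rec$channel_names))
  tibble::tibble(
    epoch = grid$epoch,
    channel = rec$channel_names[grid$ch],
    stage = if (is.null(labels)) {
      stage_factor(rep(NA_character_, nrow(grid)))
    } else {
      labels[grid$epoch + 1L]
    },
    fs = rec$fs,
    signal = purrr::map2(grid$ch, grid$epoch, function(ch, e) {
      rec$samples[ch, (e * len + 1L):((e + 1L) * len)]
    })
  )
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(name, " must be a single positive number", call. = FALSE)
  }
  invisible(x)
}
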