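#' Bump mother wavelet
#'
#' Analytic wavelet whose Fourier transform is a compactly supported bump
#' centered at `mu` with half-width `sigma` (in radians per sample once
#' scaled). Its narrow frequency variance is what makes it attractive for
#' EEG scalograms. Admissibility requires `mu - sigma > 0`, which keeps the
#' support strictly positive (zero mean, analytic).
#'
#' @param mu Center parameter (dimensionless). Default 5.
#' @param sigma Window parameter (dimensionless, > 0). Default 0.6.
#' @return A `bump_wavelet` with derived center frequency
#'   `fc = mu / (2*pi)` in cycles/sample.
#' @export
#' @examples
#' w <- bump_wavelet()
#' w$fc * 2 * pi   # = mu
bump_wavelet <- function(mu = 5, sigma = 0.6) {
  if (!(sigma > 0)) stop("sigma must be > 0", call. = FALSE)
  if (!(mu - sigma > 0)) {
    stop("mu - sigma must be > 0 for an admissible bump wavelet",
         call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, fc = mu / (2 * pi)),
            class = "bump_wavelet")
}

#' Frequency-domain bump window
#'
#' Evaluates the bump wavelet's Fourier transform at scaled angular
#' frequency `omega_scaled` (= scale times omega):
#' `exp(1 - 1/(1 - w^2))` for `|w| < 1` with
#' `w = (omega_scaled - mu) / sigma`, and 0 outside. Total function: the
#' peak value at the center is exactly 1 and the support is the open
#' interval `(mu - sigma, mu + sigma)`.
#'
#' @param omega_scaled Numeric vector of scaled angular frequencies.
#' @param wavelet A [bump_wavelet()].
#' @return Numeric vector of window values in `[0, 1]`.
#' @export
bump_fourier <- function(omega_scaled, wavelet = bump_wavelet()) {
  w <- (omega_scaled - wavelet$mu) / wavelet$sigma
  out <- numeric(length(w))
  inside <- is.finite(w) & abs(w) < 1
  out[inside] <- exp(1 - 1 / (1 - w[inside]^2))
  out
}

#' Convert wavelet scale to physical frequency
#'
#' `F = Fc * Fs / a`: a wavelet at scale `a` concentrates its energy at
#' the physical frequency `F`, given the mother wavelet's center frequency
#' `Fc` (cycles/sample) and the sampling rate `Fs` (Hz).
#'
#' @param a Scale (positive).
#' @param fc Center frequency of the mother wavelet, cycles/sample.
#' @param fs Sampling rate, Hz.
#' @return Frequency in Hz.
#' @export
#' @examples
#' scale_to_frequency(200, fc = 1, fs = 200)  # 1 Hz
scale_to_frequency <- function(a, fc, fs) {
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("scale a must be positive", call. = FALSE)
  }
  fc * fs / a
}

#' Build a geometric scale grid
#'
#' Scales spaced at `voices_per_octave` per frequency octave covering
#' `[f_min, f_max]`; the highest-frequency endpoint maps exactly to
#' `f_max` and the grid extends down to within one voice of `f_min`.
#'
#' @param f_min,f_max Frequency band in Hz, `0 < f_min < f_max <= fs/2`.
#'   Defaults 0.5-32 Hz, covering the 0.3-30 Hz preprocessed band (the
#'   0.5 Hz floor keeps the wavelet support usable on 30-s epochs).
#' @param voices_per_octave Scales per octave (default 12).
#' @param fs Sampling rate, Hz.
#' @param wavelet A [bump_wavelet()].
#' @return A `scale_grid`: list with `scales` (increasing), `frequencies`
#'   (decreasing, Hz), `voices_per_octave`, `f_min`, `f_max`, `fs`.
#' @export
#' @examples
#' g <- build_scale_grid(0.5, 32, 12, fs = 200)
#' length(g$scales)  # 73 = 12 * log2(64) + 1
build_scale_grid <- function(f_min = 0.5, f_max = 32, voices_per_octave = 12,
                             fs = 200, wavelet = bump_wavelet()) {
  check_scalar_pos(fs, "fs")
  if (!(f_min > 0 && f_min < f_max && f_max <= fs / 2)) {
    stop("need 0 < f_min < f_max <= fs/2 = ", fs / 2, call. = FALSE)
  }
  if (voices_per_octave < 1) {
    stop("voices_per_octave must be >= 1", call. = FALSE)
  }
  n_oct <- log2(f_max / f_min)
  n <- as.integer(floor(voices_per_octave * n_oct + 1e-9)) + 1L
  freqs <- f_max * 2^(-(seq_len(n) - 1L) / voices_per_octave)
  scales <- wavelet$fc * fs / freqs
  structure(
    list(scales = scales, frequencies = freqs,
         voices_per_octave = voices_per_octave,
         f_min = f_min, f_max = f_max, fs = fs),
    class = "scale_grid"
  )
}

#' Continuous wavelet transform of one epoch
#'
#' Computes `C_a(b) = (1/sqrt(a)) * sum_t x[t] conj(phi((t - b)/a))` for
#' every scale on the grid by frequency-domain multiplication: FFT of the
#' signal times the conjugate scaled wavelet window, inverse FFT. The
#' bump wavelet is analytic (support on positive frequencies only) and
#' boundary handling is the periodic extension implicit in FFT
#' convolution. Returns the scalogram (transform magnitude).
#'
#' @param epoch Numeric vector (the epoch samples, length >= 2), or a
#'   one-row of the tibble produced by [segment_epochs()] via its `signal`
#'   entry.
#' @param grid A [build_scale_grid()].
#' @param wavelet A [bump_wavelet()].
#' @return A `scalogram`: list with `magnitude` (n_scales x n_times),
#'   `frequencies` (Hz, per row), `times` (s, per column), `fs`.
#' @export
cwt_epoch <- function(epoch, grid, wavelet = bump_wavelet()) {
  stopifnot(inherits(grid, "scale_grid"))
  fs <- grid$fs
  x <- as.numeric(epoch)
  if (length(x) < 2) {
    stop("epoch must contain at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("epoch contains non-finite samples", call. = FALSE)
  n <- length(x)
  X <- stats::fft(x)
  omega <- 2 * pi * (seq_len(n) - 1L) / n
  mag <- matrix(0, nrow = length(grid$scales), ncol = n)
  for (i in seq_along(grid$scales)) {
    a <- grid$scales[i]
    win <- sqrt(a) * bump_fourier(a * omega, wavelet)
    # window is real, so conj() is a no-op; kept explicit for the contract
    C <- stats::fft(X * Conj(win), inverse = TRUE) / n
    mag[i, ] <- Mod(C)
  }
  structure(
    list(magnitude = mag, frequencies = grid$frequencies,
         times = (seq_len(n) - 1L) / fs, fs = fs),
    class = "scalogram"
  )
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d scales (%.3g-%.3g Hz) x %d samples @ %g Hz\n",
              nrow(x$magnitude), min(x$frequencies), max(x$frequencies),
              ncol(x$magnitude), x$fs))
  invisible(x)
}
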