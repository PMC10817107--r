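test_that("bump window peaks at 1, has compact symmetric support", {
  w <- bump_wavelet(mu = 5, sigma = 0.6)
  expect_equal(bump_fourier(5, w), 1)
  expect_equal(bump_fourier(5 + 0.6, w), 0)
  expect_equal(bump_fourier(5 - 0.6, w), 0)
  expect_equal(bump_fourier(c(0, 4.39, 5.61, 100), w), rep(0, 4))
  d <- seq(0.05, 0.55, by = 0.05)
  expect_equal(bump_fourier(5 + d, w), bump_fourier(5 - d, w))
  expect_true(all(bump_fourier(seq(0, 10, by = 0.01), w) <= 1))
  expect_error(bump_wavelet(mu = 1, sigma = 2), "admissible")
  expect_error(bump_wavelet(sigma = 0), "sigma")
})

test_that("scale-to-frequency conversion follows F = Fc * Fs / a", {
  expect_equal(scale_to_frequency(200, fc = 1, fs = 200), 1)
  expect_equal(scale_to_frequency(15.9155, fc = 5 / (2 * pi), fs = 200), 10,
               tolerance = 1e-4)
  a <- 7.3
  expect_equal(scale_to_frequency(a / 2, 0.8, 200),
               2 * scale_to_frequency(a, 0.8, 200))
  expect_error(scale_to_frequency(0, 1, 200), "positive")
  expect_error(scale_to_frequency(-3, 1, 200), "positive")
})

test_that("scale grids have the geometric voice structure", {
  g <- build_scale_grid(0.5, 32, 12, fs = 200)
  expect_equal(length(g$scales), 12 * log2(32 / 0.5) + 1)   # 73
  # independent loop construction of the same grid
  fr <- 32
  freqs <- fr
  while (fr / 2^(1 / 12) >= 0.5 * (1 - 1e-12)) {
    fr <- fr / 2^(1 / 12)
    freqs <- c(freqs, fr)
  }
  expect_equal(g$frequencies, freqs, tolerance = 1e-9)
  expect_true(all(diff(g$frequencies) < 0))
  expect_true(all(diff(g$scales) > 0))
  # mapped frequencies recover from scales through the conversion
  w <- bump_wavelet()
  expect_equal(scale_to_frequency(g$scales, w$fc, 200), g$frequencies)

  expect_equal(length(build_scale_grid(1, 2, 1, 200)$scales), 2)
  expect_error(build_scale_grid(2, 1, 12, 200), "f_min")
  expect_error(build_scale_grid(0.5, 150, 12, 200), "fs/2")
})

test_that("FFT-based transform matches direct integration of the CWT sum", {
  # oracle: time-domain wavelet from the inverse FFT of the scaled bump
  # window, then explicit O(N^2) circular cross-correlation
  set.seed(14)
  n <- 256
  fs <- 64
  x <- rnorm(n)
  w <- bump_wavelet()
  g <- build_scale_grid(2, 16, 2, fs = fs, wavelet = w)
  g$scales <- g$scales[1:7]
  g$frequencies <- g$frequencies[1:7]
  sc <- cwt_epoch(x, g, w)

  omega <- 2 * pi * (seq_len(n) - 1) / n
  for (si in seq_along(g$scales)) {
    a <- g$scales[si]
    wav_t <- stats::fft(sqrt(a) * bump_fourier(a * omega, w),
                        inverse = TRUE) / n
    direct <- vapply(seq_len(n) - 1L, function(b) {
      idx <- ((seq_len(n) - 1L - b) %% n) + 1L
      Mod(sum(x * Conj(wav_t[idx])))
    }, numeric(1))
    expect_equal(sc$magnitude[si, ], direct, tolerance = 1e-6)
  }
})

test_that("the ridge of a pure sinusoid lands within one voice of its frequency", {
  fs <- 200
  g <- build_scale_grid(0.5, 32, 12, fs = fs)
  t <- seq(0, by = 1 / fs, length.out = 6000)
  for (f0 in c(1.3, 4, 10, 25)) {
    sc <- cwt_epoch(sin(2 * pi * f0 * t), g)
    ridge <- g$frequencies[which.max(rowMeans(sc$magnitude))]
    expect_lt(abs(log2(ridge / f0)), 1 / 12 + 1e-9)
  }
})

test_that("the transform is linear and preserves zero", {
  fs <- 100
  g <- build_scale_grid(1, 16, 4, fs = fs)
  zero <- cwt_epoch(numeric(500), g)
  expect_true(all(zero$magnitude == 0))

  set.seed(3)
  x <- rnorm(500)
  m1 <- cwt_epoch(x, g)$magnitude
  m2 <- cwt_epoch(2 * x, g)$magnitude
  expect_equal(m2, 2 * m1, tolerance = 1e-10)

  expect_error(cwt_epoch(1, g), "2 samples")
  expect_error(cwt_epoch(c(1, NA, 3), g), "non-finite")
})

test_that("rendered images are 64x64x3 in [0,1] with degenerate fallback", {
  fs <- 100
  g <- build_scale_grid(1, 16, 8, fs = fs)
  t <- seq(0, by = 1 / fs, length.out = 900)
  sc <- cwt_epoch(sin(2 * pi * 5 * t) + 0.1 * rnorm(900), g)
  img <- render_image(sc)
  expect_equal(dim(img), c(64, 64, 3))
  expect_true(all(img >= 0 & img <= 1))
  expect_true(all(is.finite(img)))

  img2 <- render_image(sc, size = 32)
  expect_equal(dim(img2), c(32, 32, 3))

  # constant scalogram maps every pixel to the colormap's zero color
  const <- sc
  const$magnitude[] <- 3.7
  imgc <- render_image(const)
  lut <- viridis_lut()
  for (k in 1:3) {
    expect_equal(as.vector(imgc[, , k]), rep(unname(lut[1, k]), 64 * 64),
                 tolerance = 1e-9)
  }

  bad <- sc
  bad$magnitude[1, 1] <- NaN
  expect_error(render_image(bad), "non-finite")
})

test_that("antialiased resize preserves constants and the mean", {
  m <- matrix(runif(73 * 600), 73, 600)
  r <- resize_bilinear(m, 64, 64)
  expect_equal(dim(r), c(64, 64))
  expect_equal(mean(r), mean(m), tolerance = 0.02)
  flat <- resize_bilinear(matrix(0.4, 50, 70), 16, 16)
  expect_equal(as.vector(flat), rep(0.4, 256))
})

test_that("epochs_to_images carries labels and channel through", {
  ds <- generate_dataset(1, fs = 100, seed = 2)
  imgs <- epochs_to_images(ds)
  expect_equal(nrow(imgs), 5)
  expect_equal(sort(as.character(imgs$stage)), sort(stage_levels()))
  expect_true(all(vapply(imgs$pixels, function(p) {
    all(dim(p) == c(64, 64, 3))
  }, logical(1))))
  expect_equal(attr(imgs$pixels[[1]], "channel"), "C4-A1")
})

test_that("image tree round-trips stages, channels and pixel data", {
  ds <- generate_dataset(1, fs = 100, seed = 6)
  imgs <- epochs_to_images(ds)
  dir <- withr::local_tempdir()
  paths <- write_image_tree(imgs, dir)
  expect_length(paths, 5)
  back <- read_image_tree(dir)
  expect_equal(nrow(back), 5)
  expect_setequal(as.character(back$stage), stage_levels())
  key_in <- order(imgs$epoch)
  key_out <- order(back$epoch)
  for (i in 1:5) {
    expect_equal(unclass(back$pixels[[key_out[i]]]),
                 unclass(imgs$pixels[[key_in[i]]]),
                 tolerance = 1 / 255, ignore_attr = TRUE)
  }
})
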