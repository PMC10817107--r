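#' Shipped 256-entry viridis lookup table
#'
#' The colormap used to turn normalized scalogram magnitude into RGB. A
#' fixed table is shipped with the package so rendered images are
#' identical across platforms and graphics stacks.
#'
#' @return 256 x 3 numeric matrix, values in `[0, 1]`, columns R, G, B.
#' @export
viridis_lut <- function() {
  path <- system.file("extdata", "viridis256.csv", package = "sleepwave")
  lut <- as.matrix(utils::read.csv(path))
  storage.mode(lut) <- "double"
  colnames(lut) <- c("r", "g", "b")
  lut
}

# Antialiased bilinear resampling weights: triangular kernel whose support
# widens by the downscale factor, rows normalized to sum 1 (so convex
# combinations keep values in range).
resize_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  support <- max(1, scale)
  centers <- (seq_len(n_out) - 0.5) * scale - 0.5
  W <- matrix(0, n_out, n_in)
  src <- seq_len(n_in) - 1
  for (i in seq_len(n_out)) {
    w <- pmax(0, 1 - abs(src - centers[i]) / support)
    W[i, ] <- w / sum(w)
  }
  W
}

#' Antialiased bilinear resize of a matrix or RGB array
#'
#' Separable linear resampling with a triangular kernel whose support
#' scales with the downsampling factor, i.e. bilinear interpolation with
#' antialiasing. Implemented as two small weight-matrix multiplications.
#'
#' @param x Numeric matrix or 3-d array (h x w x channels).
#' @param out_h,out_w Output dimensions in pixels.
#' @return Resized matrix or array.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  Wh <- resize_weights(d[1], out_h)
  Ww <- resize_weights(d[2], out_w)
  if (length(d) == 2) return(Wh %*% x %*% t(Ww))
  out <- array(0, c(out_h, out_w, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- Wh %*% x[, , k] %*% t(Ww)
  out
}

#' Render a scalogram as a fixed-size RGB stage image
#'
#' Per-image min-max normalization of the magnitude to `[0, 1]`, colormap
#' lookup to RGB, then antialiased bilinear resize to `size x size`. A
#' constant scalogram (degenerate min = max) maps to the colormap's zero
#' color. Rows are ordered so that the highest frequency is the top image
#' row.
#'
#' @param scal A `scalogram` from [cwt_epoch()].
#' @param size Output side length in pixels (default 64, the network's
#'   input size).
#' @param colormap 256 x 3 lookup table in `[0, 1]` (default
#'   [viridis_lut()]).
#' @param label Optional stage token attached to the image.
#' @param channel Optional source-channel string attached to the image.
#' @return A `stage_image`: `size x size x 3` array in `[0, 1]` with
#'   attributes `stage` and `channel`.
#' @export
render_image <- function(scal, size = 64, colormap = viridis_lut(),
                         label = NULL, channel = NULL) {
  stopifnot(inherits(scal, "scalogram"))
  mag <- scal$magnitude
  if (length(mag) == 0) stop("scalogram is empty", call. = FALSE)
  if (any(!is.finite(mag))) {
    stop("scalogram contains non-finite magnitudes", call. = FALSE)
  }
  rng <- range(mag)
  v <- if (rng[2] > rng[1]) (mag - rng[1]) / (rng[2] - rng[1]) else mag * 0
  # highest frequency on top: frequencies are stored in decreasing order,
  # which already matches image row order
  idx <- pmin(256L, 1L + as.integer(floor(v * 255)))
  rgb <- array(0, c(nrow(v), ncol(v), 3))
  for (k in 1:3) rgb[, , k] <- matrix(colormap[idx, k], nrow(v), ncol(v))
  px <- resize_bilinear(rgb, size, size)
  px[px < 0] <- 0
  px[px > 1] <- 1
  structure(px, class = "stage_image",
            stage = if (is.null(label)) NA_character_ else as.character(label),
            channel = if (is.null(channel)) NA_character_ else channel)
}

#' @export
print.stage_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<stage_image> %dx%dx%d, stage = %s, channel = %s\n",
              d[1], d[2], d[3], attr(x, "stage"), attr(x, "channel")))
  invisible(x)
}

#' Convert an epoch table to a scalogram-image dataset
#'
#' Maps every row of a [segment_epochs()] / [generate_dataset()] tibble
#' through the bump-wavelet transform and image renderer.
#'
#' @param epochs Tibble with list-column `signal` plus `stage`, `channel`,
#'   `fs` columns.
#' @param grid A [build_scale_grid()]; defaults to the standard 0.5-32 Hz,
#'   12-voice grid at the table's sampling rate.
#' @param wavelet A [bump_wavelet()].
#' @param size Image side length (default 64).
#' @param colormap Colormap lookup table.
#' @return The input tibble with the `signal` column replaced by a
#'   `pixels` list-column of `size x size x 3` arrays.
#' @export
epochs_to_images <- function(epochs, grid = NULL, wavelet = bump_wavelet(),
                             size = 64, colormap = viridis_lut()) {
  stopifnot(nrow(epochs) > 0, "signal" %in% names(epochs))
  fs <- epochs$fs[1]
  if (is.null(grid)) grid <- build_scale_grid(fs = fs, wavelet = wavelet)
  pixels <- purrr::pmap(
    list(epochs$signal, as.character(epochs$stage), epochs$channel),
    function(sig, st, ch) {
      render_image(cwt_epoch(sig, grid, wavelet), size = size,
                   colormap = colormap, label = st, channel = ch)
    }
  )
  out <- dplyr::select(epochs, -"signal")
  out$pixels <- pixels
  out
}

#' Write an image dataset as a PNG directory tree
#'
#' One file per epoch, laid out `<out_dir>/<channel>/<stage>/<epoch>.png`
#' so each image sits in its label's folder.
#'
#' @param images Tibble from [epochs_to_images()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_image_tree <- function(images, out_dir) {
  stopifnot(all(c("pixels", "stage", "channel", "epoch") %in% names(images)))
  paths <- character(nrow(images))
  for (i in seq_len(nrow(images))) {
    d <- file.path(out_dir, images$channel[i], as.character(images$stage[i]))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(d, sprintf("%06d.png", images$epoch[i]))
    png::writePNG(unclass(images$pixels[[i]]), paths[i])
  }
  invisible(paths)
}

#' Read a PNG directory tree back as an image dataset
#'
#' Inverse of [write_image_tree()]: expects
#' `<dir>/<channel>/<stage>/<epoch>.png`.
#'
#' @param dir Root directory.
#' @return Tibble with `epoch`, `channel`, `stage`, `pixels` columns.
#' @export
read_image_tree <- function(dir) {
  files <- list.files(dir, pattern = "\\.png$", recursive = TRUE,
                      full.names = TRUE)
  if (length(files) == 0) stop("no PNG files under ", dir, call. = FALSE)
  parts <- strsplit(sub(paste0("^", dir, "/?"), "", files), "/")
  bad <- lengths(parts) != 3
  if (any(bad)) {
    stop("unexpected layout (want <channel>/<stage>/<epoch>.png): ",
         files[bad][1], call. = FALSE)
  }
  tibble::tibble(
    epoch = as.integer(sub("\\.png$", "", vapply(parts, `[`, "", 3))),
    channel = vapply(parts, `[`, "", 1),
    stage = stage_factor(vapply(parts, `[`, "", 2)),
    pixels = lapply(files, function(f) {
      px <- png::readPNG(f)
      structure(px, class = "stage_image")
    })
  )
}
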