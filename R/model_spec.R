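#' Layer specification helpers
#'
#' Constructors for the layer records a [cnn_spec()] is built from. Only
#' the parameters meaningful for each kind are stored.
#'
#' @name layer_spec
#' @param size Input side/channels for the input layer, length-3
#'   `c(h, w, channels)`.
#' @param n_filters,kernel Convolution filter count and square kernel
#'   size.
#' @param n_channels Batch-norm channel count.
#' @param pool,stride Max-pool kernel and stride.
#' @param units Fully-connected output count.
#' @return A `list` describing one layer.
NULL

#' @rdname layer_spec
#' @export
layer_input <- function(size = c(64, 64, 3)) {
  stopifnot(length(size) == 3, all(size >= 1))
  list(kind = "input", size = as.integer(size))
}

#' @rdname layer_spec
#' @export
layer_conv <- function(n_filters, kernel) {
  stopifnot(n_filters >= 1, kernel >= 1)
  list(kind = "conv", n_filters = as.integer(n_filters),
       kernel = as.integer(kernel))
}

#' @rdname layer_spec
#' @export
layer_batch_norm <- function(n_channels) {
  stopifnot(n_channels >= 1)
  list(kind = "batch_norm", n_channels = as.integer(n_channels))
}

#' @rdname layer_spec
#' @export
layer_relu <- function() list(kind = "relu")

#' @rdname layer_spec
#' @export
layer_max_pool <- function(pool, stride) {
  stopifnot(pool >= 1, stride >= 1)
  list(kind = "max_pool", pool = as.integer(pool), stride = as.integer(stride))
}

#' @rdname layer_spec
#' @export
layer_fully_connected <- function(units = 5) {
  stopifnot(units >= 1)
  list(kind = "fully_connected", units = as.integer(units))
}

#' @rdname layer_spec
#' @export
layer_softmax <- function() list(kind = "softmax")

#' @rdname layer_spec
#' @export
layer_classification <- function() list(kind = "classification")

#' Assemble a CNN architecture specification
#'
#' @param layers List of layer records built with the [layer_spec]
#'   helpers, input layer first.
#' @param padding Convolution padding policy; only `"same"` (stride-1
#'   convolutions preserving the spatial size) is implemented.
#' @param init Weight initialization policy; `"glorot_normal"` draws
#'   zero-mean Gaussians with variance `2 / (fan_in + fan_out)`.
#' @return A `cnn_spec`.
#' @export
cnn_spec <- function(layers, padding = "same", init = "glorot_normal") {
  stopifnot(is.list(layers))
  padding <- match.arg(padding, "same")
  init <- match.arg(init, "glorot_normal")
  structure(list(layers = layers, padding = padding, init = init),
            class = "cnn_spec")
}

#' The default 19-layer architecture
#'
#' Four convolution blocks (conv + batch norm + ReLU) with filter counts
#' 128, 64, 32, 16 and kernels 7x7, 5x5, 3x3, 3x3, max pools of 3x3, 3x3
#' and 2x2 (all stride 2) after the first three blocks, then a 5-way fully
#' connected layer, softmax, and the cross-entropy classification head
#' (identity at inference). With "same" padding and ceil-mode pooling the
#' spatial trace is 64 -> 32 -> 16 -> 8 before the fully connected layer.
#' Convolution layers are linear; the separate ReLU layers carry the
#' activations.
#'
#' @return A `cnn_spec` with exactly 19 layers.
#' @export
#' @examples
#' count_layers(default_model_spec())  # 19
default_model_spec <- function() {
  cnn_spec(list(
    layer_input(c(64, 64, 3)),
    layer_conv(128, 7),
    layer_batch_norm(128),
    layer_relu(),
    layer_max_pool(3, 2),
    layer_conv(64, 5),
    layer_batch_norm(64),
    layer_relu(),
    layer_max_pool(3, 2),
    layer_conv(32, 3),
    layer_batch_norm(32),
    layer_relu(),
    layer_max_pool(2, 2),
    layer_conv(16, 3),
    layer_batch_norm(16),
    layer_relu(),
    layer_fully_connected(5),
    layer_softmax(),
    layer_classification()
  ))
}

#' Number of layers in a specification
#'
#' @param spec A `cnn_spec`.
#' @return Integer layer count.
#' @export
count_layers <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  length(spec$layers)
}

# Trace input geometry through the layers; returns per-layer output dims
# (h, w, c) plus derived fields (conv in_channels, fc in_features).
spec_geometry <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  layers <- spec$layers
  if (length(layers) == 0) return(list())
  if (layers[[1]]$kind != "input") {
    stop("spec must start with an input layer", call. = FALSE)
  }
  h <- layers[[1]]$size[1]; w <- layers[[1]]$size[2]; c <- layers[[1]]$size[3]
  geom <- vector("list", length(layers))
  flat <- FALSE
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    extra <- list()
    switch(ly$kind,
      input = {},
      conv = {
        if (flat) stop("conv layer after flattening", call. = FALSE)
        extra$in_channels <- c
        c <- ly$n_filters
      },
      batch_norm = {
        if (ly$n_channels != c) {
          stop("batch_norm layer ", i, " declares ", ly$n_channels,
               " channels but receives ", c, call. = FALSE)
        }
      },
      relu = {},
      max_pool = {
        h <- ceiling((h - ly$pool) / ly$stride) + 1L
        w <- ceiling((w - ly$pool) / ly$stride) + 1L
      },
      fully_connected = {
        extra$in_features <- h * w * c
        flat <- TRUE
        h <- 1L; w <- 1L; c <- ly$units
      },
      softmax = {},
      classification = {},
      stop("unknown layer kind: ", ly$kind, call. = FALSE)
    )
    geom[[i]] <- c(list(kind = ly$kind, h = as.integer(h), w = as.integer(w),
                        c = as.integer(c)), extra)
  }
  geom
}

#' Trainable parameter counts per layer
#'
#' Computed from the architecture arithmetic: a convolution holds
#' `k*k*c_in*c_out + c_out` parameters, batch norm `2*c` (scale and
#' shift), the fully connected layer `in*out + out`; other layers hold
#' none.
#'
#' @param spec A `cnn_spec`.
#' @return Tibble with `layer`, `kind`, `n_params`.
#' @export
layer_parameter_counts <- function(spec) {
  geom <- spec_geometry(spec)
  layers <- spec$layers
  n <- vapply(seq_along(layers), function(i) {
    ly <- layers[[i]]
    switch(ly$kind,
      conv = ly$kernel^2 * geom[[i]]$in_channels * ly$n_filters + ly$n_filters,
      batch_norm = 2L * ly$n_channels,
      fully_connected = geom[[i]]$in_features * ly$units + ly$units,
      0L
    )
  }, numeric(1))
  tibble::tibble(layer = seq_along(layers),
                 kind = vapply(layers, `[[`, "", "kind"),
                 n_params = as.numeric(n))
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec> %d layers, padding = %s, init = %s\n",
              count_layers(x), x$padding, x$init))
  pc <- layer_parameter_counts(x)
  cat(sprintf("  trainable parameters: %s\n",
              format(sum(pc$n_params), big.mark = ",")))
  invisible(x)
}
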