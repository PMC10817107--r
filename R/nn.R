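# Neural-network engine: parameter container, spec-driven forward /
# backward passes, Adam optimizer, training loop.
#
# Activations are column-major arrays (H, W, C, B). Convolutions run as
# per-image im2col + BLAS GEMM; batch norm, ReLU and pooling are fused
# C++ kernels. Because this engine targets single-CPU machines where
# large allocations dominate runtime, every bulky intermediate (patch
# matrices, activation planes, gradient planes) lives in a buffer pool
# keyed by layer and shape and is recycled across iterations; all writes
# into pooled buffers go through the C++ kernels.
#
# Batch statistics for batch norm are taken over the sub-batch actually
# materialized in memory (a "ghost batch", default 16 images), while the
# optimizer accumulates gradients over the full configured mini-batch
# before each Adam step.

.nn_buf <- new.env(parent = emptyenv())

buf_matrix <- function(key, nr, nc) {
  b <- .nn_buf[[key]]
  if (is.null(b) || nrow(b) != nr || ncol(b) != nc) {
    b <- matrix(0, nr, nc)
    .nn_buf[[key]] <- b
  }
  b
}

buf_array <- function(key, dims) {
  b <- .nn_buf[[key]]
  if (is.null(b) || !identical(dim(b), as.integer(dims))) {
    b <- array(0, dims)
    .nn_buf[[key]] <- b
  }
  b
}

buf_int <- function(key, n) {
  b <- .nn_buf[[key]]
  if (is.null(b) || length(b) != n) {
    b <- integer(n)
    .nn_buf[[key]] <- b
  }
  b
}

#' Build an initialized (untrained) model from a specification
#'
#' Weights are drawn from zero-mean Gaussians with glorot (fan-based)
#' variance `2 / (fan_in + fan_out)`; biases start at zero; batch-norm
#' scale/shift at 1/0 with running statistics 0/1. Two builds with the
#' same seed are identical.
#'
#' @param spec A [cnn_spec()] (default [default_model_spec()]).
#' @param seed Integer seed for the weight draws.
#' @return A `sleep_cnn` model object.
#' @export
#' @examples
#' m <- build_model(default_model_spec(), seed = 1)
#' sum(layer_parameter_counts(m$spec)$n_params)
build_model <- function(spec = default_model_spec(), seed = 1L) {
  geom <- spec_geometry(spec)   # also validates the spec
  set.seed(as.integer(seed))
  params <- vector("list", length(spec$layers))
  state <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv") {
      cin <- geom[[i]]$in_channels
      k <- ly$kernel
      fan_in <- k * k * cin
      fan_out <- k * k * ly$n_filters
      sd <- sqrt(2 / (fan_in + fan_out))
      params[[i]] <- list(
        W = matrix(stats::rnorm(fan_in * ly$n_filters, sd = sd),
                   nrow = fan_in, ncol = ly$n_filters),
        b = numeric(ly$n_filters)
      )
    } else if (ly$kind == "batch_norm") {
      params[[i]] <- list(gamma = rep(1, ly$n_channels),
                          beta = numeric(ly$n_channels))
      state[[i]] <- list(mean = numeric(ly$n_channels),
                         var = rep(1, ly$n_channels))
    } else if (ly$kind == "fully_connected") {
      fin <- geom[[i]]$in_features
      sd <- sqrt(2 / (fin + ly$units))
      params[[i]] <- list(
        W = matrix(stats::rnorm(fin * ly$units, sd = sd),
                   nrow = fin, ncol = ly$units),
        b = numeric(ly$units)
      )
    }
  }
  structure(
    list(spec = spec, params = params, state = state, geometry = geom,
         classes = stage_levels(), history = NULL, trained = FALSE),
    class = "sleep_cnn"
  )
}

#' @export
print.sleep_cnn <- function(x, ...) {
  pc <- layer_parameter_counts(x$spec)
  cat(sprintf("<sleep_cnn> %d layers, %s trainable parameters, %s\n",
              count_layers(x$spec),
              format(sum(pc$n_params), big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  if (!is.null(x$history)) {
    cat(sprintf("  training: %d iterations, final loss %.4f\n",
                nrow(x$history), utils::tail(x$history$loss, 1)))
  }
  invisible(x)
}

BN_EPS <- 1e-5

net_forward <- function(model, x, train = FALSE, keep_cache = train,
                        bn_momentum = 0.1, bn_collect = NULL) {
  layers <- model$spec$layers
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  state <- model$state
  dims <- NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "input") {
      d <- dim(x)
      if (is.null(d) || length(d) < 3 || !all(d[1:3] == ly$size)) {
        stop("input images must have shape ",
             paste(ly$size, collapse = "x"), call. = FALSE)
      }
      if (length(d) == 3) dim(x) <- c(d, 1L)
      dims <- dim(x)
    } else if (ly$kind == "conv") {
      p <- model$params[[i]]
      H <- dims[1]; W <- dims[2]; C <- dims[3]; B <- dims[4]
      k <- ly$kernel; pad <- (k - 1L) %/% 2L
      hw <- H * W
      P <- buf_matrix(sprintf("P%d", i), hw, k * k * C)
      Y <- buf_matrix(sprintf("Y%d", i), hw, ly$n_filters)
      out <- buf_array(sprintf("convout%d_%d", i, B),
                       c(H, W, ly$n_filters, B))
      for (img in seq_len(B) - 1L) {
        im2col_img_cpp(P, x, H, W, C, img, k, k, pad, pad)
        gemm_cpp(Y, P, p$W, FALSE, FALSE, 0)
        set_conv_out_cpp(out, Y, img, p$b)
      }
      if (keep_cache) cache[[i]] <- list(x = x, dims = dims)
      x <- out
      dims <- c(H, W, ly$n_filters, B)
    } else if (ly$kind == "batch_norm") {
      p <- model$params[[i]]
      hw <- dims[1] * dims[2]; C <- dims[3]; B <- dims[4]
      out <- buf_array(sprintf("bnout%d_%d", i, B), dims)
      if (train) {
        n <- hw * B
        s <- bn_stats_cpp(x, hw, C, B)
        mu <- s[1, ] / n
        v <- pmax(s[2, ] / n - mu^2, 0)
        inv_std <- 1 / sqrt(v + BN_EPS)
        A <- inv_std * p$gamma
        bn_affine_cpp(out, x, A, p$beta - mu * A, hw, C, B)
        state[[i]]$mean <- (1 - bn_momentum) * state[[i]]$mean +
          bn_momentum * mu
        state[[i]]$var <- (1 - bn_momentum) * state[[i]]$var +
          bn_momentum * v * n / max(1, n - 1)
        if (!is.null(bn_collect)) {
          key <- as.character(i)
          bn_collect$sums[[key]] <- (bn_collect$sums[[key]] %||% 0) + s
          bn_collect$n[[key]] <- (bn_collect$n[[key]] %||% 0) + n
        }
        if (keep_cache) {
          cache[[i]] <- list(x = x, mu = mu, inv_std = inv_std,
                             hw = hw, dims = dims)
        }
      } else {
        inv_std <- 1 / sqrt(state[[i]]$var + BN_EPS)
        A <- inv_std * p$gamma
        bn_affine_cpp(out, x, A, p$beta - state[[i]]$mean * A, hw, C, B)
      }
      x <- out
    } else if (ly$kind == "relu") {
      relu_cpp(x)    # in place on this layer's input buffer
      if (keep_cache) cache[[i]] <- list(out = x)
    } else if (ly$kind == "max_pool") {
      H <- dims[1]; W <- dims[2]; C <- dims[3]; B <- dims[4]
      Oh <- (H - ly$pool + ly$stride - 1L) %/% ly$stride + 1L
      Ow <- (W - ly$pool + ly$stride - 1L) %/% ly$stride + 1L
      out <- buf_array(sprintf("poolout%d_%d", i, B), c(Oh, Ow, C, B))
      idx <- buf_int(sprintf("poolidx%d_%d", i, B), Oh * Ow * C * B)
      maxpool_fill_cpp(out, idx, x, H, W, C, B, ly$pool, ly$stride)
      if (keep_cache) cache[[i]] <- list(idx = idx, in_dim = dims)
      x <- out
      dims <- c(Oh, Ow, C, B)
    } else if (ly$kind == "fully_connected") {
      p <- model$params[[i]]
      B <- dims[4]
      xf <- matrix(x, nrow = prod(dims[1:3]), ncol = B)
      if (keep_cache) cache[[i]] <- list(x = xf, in_dim = dims)
      x <- crossprod(xf, p$W) + rep(p$b, each = B)   # B x units
      dims <- NULL
    } else if (ly$kind == "softmax") {
      x <- x - apply(x, 1, max)
      x <- exp(x)
      x <- x / rowSums(x)
      if (keep_cache) cache[[i]] <- list(probs = x)
    }
    # classification layer: identity at inference, loss head in training
  }
  list(probs = x, cache = cache, state = state)
}

# Backward pass from softmax + cross-entropy; `scale` divides the
# gradient (the full mini-batch size when accumulating over sub-batches).
# Returns per-layer parameter gradients (fresh objects, safe to
# accumulate) aligned with model$params.
net_backward <- function(model, cache, onehot, scale,
                         sample_weights = NULL) {
  layers <- model$spec$layers
  grads <- vector("list", length(layers))
  g <- NULL
  gdims <- NULL
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$kind == "classification") {
      next
    } else if (ly$kind == "softmax") {
      g <- (cache[[i]]$probs - onehot) / scale
      if (!is.null(sample_weights)) g <- g * sample_weights
    } else if (ly$kind == "fully_connected") {
      p <- model$params[[i]]
      xf <- cache[[i]]$x
      grads[[i]] <- list(W = xf %*% g, b = colSums(g))
      g <- p$W %*% t(g)        # features x B, fresh allocation (small)
      gdims <- cache[[i]]$in_dim
    } else if (ly$kind == "max_pool") {
      cc <- cache[[i]]
      gb <- buf_array(sprintf("poolbwd%d_%d", i, cc$in_dim[4]), cc$in_dim)
      maxpool_bwd_fill_cpp(gb, g, cc$idx)
      g <- gb
      gdims <- cc$in_dim
    } else if (ly$kind == "relu") {
      relu_bwd_cpp(g, cache[[i]]$out)   # in place on g
    } else if (ly$kind == "batch_norm") {
      p <- model$params[[i]]
      cc <- cache[[i]]
      d <- cc$dims
      s <- bn_bwd_cpp(g, cc$x, cc$mu, cc$inv_std, p$gamma,
                      cc$hw, d[3], d[4])
      grads[[i]] <- list(gamma = s[1, ], beta = s[2, ])
      gdims <- d
    } else if (ly$kind == "conv") {
      p <- model$params[[i]]
      cc <- cache[[i]]
      H <- cc$dims[1]; W <- cc$dims[2]; C <- cc$dims[3]; B <- cc$dims[4]
      k <- ly$kernel; pad <- (k - 1L) %/% 2L
      hw <- H * W
      nf <- ly$n_filters
      need_dx <- i > 2L   # no gradient needed below the first conv
      P <- buf_matrix(sprintf("P%d", i), hw, k * k * C)
      Yg <- buf_matrix(sprintf("Yg%d", i), hw, nf)
      dW <- buf_matrix(sprintf("dW%d", i), k * k * C, nf)
      if (need_dx) {
        dP <- buf_matrix(sprintf("dP%d", i), hw, k * k * C)
        dx <- buf_array(sprintf("convbwd%d_%d", i, B), cc$dims)
      }
      db <- numeric(nf)
      for (img in seq_len(B) - 1L) {
        get_slice_cpp(Yg, g, img)
        im2col_img_cpp(P, cc$x, H, W, C, img, k, k, pad, pad)
        gemm_cpp(dW, P, Yg, TRUE, FALSE, if (img == 0L) 0 else 1)
        db <- db + colSums(Yg)
        if (need_dx) {
          gemm_cpp(dP, Yg, p$W, FALSE, TRUE, 0)
          col2im_img_cpp(dx, dP, H, W, C, img, k, k, pad, pad)
        }
      }
      grads[[i]] <- list(W = dW + 0, b = db)   # dW buffer is recycled: copy
      if (need_dx) {
        g <- dx
        gdims <- cc$dims
      }
    } else if (ly$kind == "input") {
      break
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(v) list(m = v * 0, v = v * 0))
  })
}

adam_step <- function(params, grads, opt, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      gr <- grads[[i]][[nm]]
      st <- opt[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * gr
      st$v <- beta2 * st$v + (1 - beta2) * gr^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      opt[[i]][[nm]] <- st
    }
  }
  list(params = params, opt = opt)
}

#' Training configuration
#'
#' Defaults follow the methodology the package implements: Adam with an
#' initial learning rate of 0.001, mini-batch size 128, up to 100 epochs,
#' a validation pass every 100 iterations.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Mini-batch size for each optimizer step (>= 1).
#' @param max_epochs Maximum passes over the training set.
#' @param validation_frequency Iterations between mid-training validation
#'   passes (validation is also evaluated at every epoch end).
#' @param seed Integer seed controlling shuffling (and nothing else; model
#'   weights are seeded by [build_model()]).
#' @param ghost_batch Sub-batch size whose statistics drive batch norm;
#'   gradients still accumulate to `batch_size` per optimizer step.
#' @param early_stop_val_acc Optional validation-accuracy target; when the
#'   epoch-end validation accuracy reaches it, training stops early.
#' @param weight_classes If TRUE, cross-entropy is weighted inversely to
#'   class frequency (off by default; the reference methodology uses
#'   unweighted loss).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128,
                         max_epochs = 100, validation_frequency = 100,
                         seed = 1L, ghost_batch = 16L,
                         early_stop_val_acc = NULL,
                         weight_classes = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 validation_frequency = as.integer(validation_frequency),
                 seed = as.integer(seed),
                 ghost_batch = as.integer(ghost_batch),
                 early_stop_val_acc = early_stop_val_acc,
                 weight_classes = isTRUE(weight_classes)),
            class = "train_config")
}

images_to_array <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  if (is.array(images) && length(dim(images)) == 3) {
    images <- unclass(images)
    dim(images) <- c(dim(images), 1L)
    return(images)
  }
  pix <- if (is.data.frame(images)) images$pixels else images
  d <- dim(pix[[1]])
  array(unlist(pix, use.names = FALSE), c(d, length(pix)))
}

images_to_labels <- function(images) {
  if (is.data.frame(images)) stage_factor(images$stage) else NULL
}

#' Train a model
#'
#' Minimizes cross-entropy with Adam. The loss of every iteration and
#' each validation accuracy are recorded in the returned model's
#' `history` tibble for curve plotting. With a fixed seed and
#' single-threaded BLAS the loss history is reproducible.
#'
#' @param model A `sleep_cnn` from [build_model()].
#' @param train_set Tibble with `pixels` list-column and `stage` column
#'   (see [epochs_to_images()]).
#' @param val_set Optional validation tibble of the same shape.
#' @param cfg A [train_config()].
#' @param verbose Print a line per epoch.
#' @return The trained model (history attached).
#' @export
train_cnn <- function(model, train_set, val_set = NULL,
                      cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "sleep_cnn"))
  n <- if (is.data.frame(train_set)) nrow(train_set) else length(train_set)
  if (n < 1) stop("training set is empty", call. = FALSE)
  y <- images_to_labels(train_set)
  if (is.null(y) || anyNA(y)) {
    stop("train_set must carry a stage label for every image", call. = FALSE)
  }
  nclass <- length(model$classes)
  ycode <- as.integer(y)
  class_w <- NULL
  if (cfg$weight_classes) {
    freq <- tabulate(ycode, nclass)
    w <- ifelse(freq > 0, 1 / freq, 0)
    class_w <- w * sum(freq) / sum(w * freq)
  }
  xall <- images_to_array(train_set)
  if (!all(dim(xall)[1:3] == model$spec$layers[[1]]$size)) {
    stop("training images do not match the model input size ",
         paste(model$spec$layers[[1]]$size, collapse = "x"), call. = FALSE)
  }
  opt <- adam_init(model$params)
  set.seed(cfg$seed)
  hist <- list()
  t_adam <- 0L
  iter <- 0L
  stopped <- FALSE
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      b1 <- min(n, b0 + cfg$batch_size - 1L)
      bidx <- perm[b0:b1]
      nb <- length(bidx)
      gacc <- NULL
      loss <- 0
      for (s0 in seq(1L, nb, by = cfg$ghost_batch)) {
        s1 <- min(nb, s0 + cfg$ghost_batch - 1L)
        sidx <- bidx[s0:s1]
        xs <- xall[, , , sidx, drop = FALSE]
        ys <- ycode[sidx]
        fw <- net_forward(model, xs, train = TRUE)
        model$state <- fw$state
        onehot <- matrix(0, length(sidx), nclass)
        onehot[cbind(seq_along(sidx), ys)] <- 1
        p_true <- fw$probs[cbind(seq_along(sidx), ys)]
        sw <- NULL
        if (!is.null(class_w)) {
          sw <- class_w[ys]
          loss <- loss + sum(-log(pmax(p_true, 1e-12)) * sw)
        } else {
          loss <- loss + sum(-log(pmax(p_true, 1e-12)))
        }
        gr <- net_backward(model, fw$cache, onehot, scale = nb,
                           sample_weights = sw)
        gacc <- if (is.null(gacc)) gr else accumulate_grads(gacc, gr)
      }
      t_adam <- t_adam + 1L
      upd <- adam_step(model$params, gacc, opt, cfg$learning_rate, t_adam)
      model$params <- upd$params
      opt <- upd$opt
      iter <- iter + 1L
      val_acc <- NA_real_
      if (!is.null(val_set) && cfg$validation_frequency > 0 &&
          iter %% cfg$validation_frequency == 0) {
        val_acc <- validation_accuracy(model, val_set)
      }
      hist[[length(hist) + 1L]] <-
        list(iteration = iter, epoch = epoch, loss = loss / nb,
             val_accuracy = val_acc)
    }
    if (!is.null(val_set)) {
      # the running-average batch-norm statistics need many updates to
      # forget their initialization; refresh them with exact population
      # moments before validating (one forward pass over the train set)
      model <- finalize_bn_stats(model, xall, cfg$ghost_batch)
      va <- validation_accuracy(model, val_set)
      hist[[length(hist)]]$val_accuracy <- va
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f, val acc %.4f", epoch,
                        hist[[length(hist)]]$loss, va))
      }
      if (!is.null(cfg$early_stop_val_acc) && va >= cfg$early_stop_val_acc) {
        stopped <- TRUE
      }
    } else if (verbose) {
      message(sprintf("epoch %d: loss %.4f", epoch,
                      hist[[length(hist)]]$loss))
    }
    if (stopped) break
  }
  model <- finalize_bn_stats(model, xall, cfg$ghost_batch)
  model$history <- dplyr::bind_rows(lapply(hist, tibble::as_tibble))
  model$trained <- TRUE
  model
}

# Replace the exponentially-averaged batch-norm statistics with exact
# population moments of each normalization layer's input over `images`,
# the standard finalization step before inference. Downstream layers see
# batch-normalized activations during the pass, as in training.
finalize_bn_stats <- function(model, xall, ghost = 16L) {
  env <- new.env(parent = emptyenv())
  env$sums <- list()
  env$n <- list()
  B <- dim(xall)[4]
  for (i0 in seq(1L, B, by = ghost)) {
    i1 <- min(B, i0 + ghost - 1L)
    net_forward(model, xall[, , , i0:i1, drop = FALSE], train = TRUE,
                keep_cache = FALSE, bn_collect = env)
  }
  for (key in names(env$sums)) {
    i <- as.integer(key)
    S <- env$sums[[key]]
    N <- env$n[[key]]
    m <- S[1, ] / N
    v <- pmax(S[2, ] / N - m^2, 0)
    model$state[[i]]$mean <- m
    model$state[[i]]$var <- v * N / max(1, N - 1)
  }
  model
}

accumulate_grads <- function(a, b) {
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

validation_accuracy <- function(model, val_set) {
  y <- images_to_labels(val_set)
  pred <- classify_stages(model, val_set)
  mean(as.character(pred) == as.character(y), na.rm = TRUE)
}

#' Class probabilities for stage images
#'
#' Forward pass in inference mode (batch norm uses running statistics).
#' Every row is non-negative and sums to one.
#'
#' @param model A `sleep_cnn`.
#' @param images Image tibble (with `pixels` list-column), list of pixel
#'   arrays, or a single `h x w x 3` array.
#' @param chunk Images per forward chunk.
#' @return Numeric matrix `n x n_classes` with stage-level column names.
#' @export
predict_proba <- function(model, images, chunk = 16L) {
  stopifnot(inherits(model, "sleep_cnn"))
  x <- images_to_array(images)
  if (!all(dim(x)[1:3] == model$spec$layers[[1]]$size)) {
    stop("images do not match the model input size ",
         paste(model$spec$layers[[1]]$size, collapse = "x"), call. = FALSE)
  }
  B <- dim(x)[4]
  fc <- Filter(function(ly) ly$kind == "fully_connected", model$spec$layers)
  nclass <- fc[[length(fc)]]$units
  out <- matrix(0, B, nclass)
  for (i0 in seq(1L, B, by = chunk)) {
    i1 <- min(B, i0 + chunk - 1L)
    fw <- net_forward(model, x[, , , i0:i1, drop = FALSE], train = FALSE,
                      keep_cache = FALSE)
    out[i0:i1, ] <- fw$probs
  }
  if (nclass == length(model$classes)) colnames(out) <- model$classes
  out
}

#' Hard stage predictions
#'
#' Argmax of [predict_proba()], ties broken toward the lowest class index
#' (i.e. the earlier stage in the canonical order).
#'
#' @inheritParams predict_proba
#' @return Factor of predicted stages.
#' @export
classify_stages <- function(model, images) {
  p <- predict_proba(model, images)
  factor(model$classes[max.col(p, ties.method = "first")],
         levels = model$classes)
}

#' @export
predict.sleep_cnn <- function(object, newdata,
                              type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "prob") predict_proba(object, newdata)
  else classify_stages(object, newdata)
}

#' Save / load a model checkpoint
#'
#' Single-file, versioned serialization of the architecture, parameters,
#' batch-norm state and training history.
#'
#' @param model A `sleep_cnn`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` invisibly returns `path`;
#'   `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sleep_cnn"))
  saveRDS(list(format = "sleepwave-checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sleepwave-checkpoint")) {
    stop("not a sleepwave checkpoint: ", path, call. = FALSE)
  }
  obj$model
}
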