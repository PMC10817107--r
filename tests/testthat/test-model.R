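test_that("the default architecture matches its printed description", {
  spec <- default_model_spec()
  expect_equal(count_layers(spec), 19)
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  convs <- spec$layers[kinds == "conv"]
  expect_length(convs, 4)
  expect_equal(vapply(convs, `[[`, integer(1), "n_filters"),
               c(128L, 64L, 32L, 16L))
  expect_equal(vapply(convs, `[[`, integer(1), "kernel"), c(7L, 5L, 3L, 3L))
  expect_equal(spec$layers[[1]]$size, c(64L, 64L, 3L))
  fc <- spec$layers[kinds == "fully_connected"]
  expect_equal(fc[[1]]$units, 5L)
  pools <- spec$layers[kinds == "max_pool"]
  expect_equal(vapply(pools, `[[`, integer(1), "pool"), c(3L, 3L, 2L))
  expect_equal(vapply(pools, `[[`, integer(1), "stride"), c(2L, 2L, 2L))
  # spatial trace 64 -> 32 -> 16 -> 8 before the fully connected layer
  geom <- sleepwave:::spec_geometry(spec)
  sizes <- vapply(geom[kinds == "max_pool"], `[[`, integer(1), "h")
  expect_equal(sizes, c(32L, 16L, 8L))
})

test_that("count_layers tracks spec edits", {
  spec <- default_model_spec()
  drop_block <- cnn_spec(spec$layers[-(2:4)])   # remove conv+BN+ReLU
  expect_equal(count_layers(drop_block), 16)
  expect_equal(count_layers(cnn_spec(list())), 0)
})

test_that("parameter counts match independent fan arithmetic", {
  pc <- layer_parameter_counts(default_model_spec())
  by_kind <- split(pc$n_params, pc$kind)
  expect_equal(pc$n_params[pc$layer == 2], 7 * 7 * 3 * 128 + 128)   # 18944
  expect_equal(pc$n_params[pc$layer == 6], 5 * 5 * 128 * 64 + 64)   # 204864
  expect_equal(pc$n_params[pc$layer == 10], 3 * 3 * 64 * 32 + 32)
  expect_equal(pc$n_params[pc$layer == 14], 3 * 3 * 32 * 16 + 16)
  expect_equal(pc$n_params[pc$layer == 17], 8 * 8 * 16 * 5 + 5)
  # framework totals equal the layer-by-layer arithmetic
  m <- build_model(default_model_spec(), seed = 1)
  built <- sum(unlist(lapply(m$params, function(p) {
    if (is.null(p)) 0 else sum(lengths(p))
  })))
  expect_equal(built, sum(pc$n_params))
})

test_that("builds are deterministic under seed and glorot-scaled", {
  m1 <- build_model(default_model_spec(), seed = 42)
  m2 <- build_model(default_model_spec(), seed = 42)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(default_model_spec(), seed = 43)
  expect_false(identical(m1$params, m3$params))
  # conv-1 weights: sd should be near sqrt(2 / (7*7*3 + 7*7*128))
  sd_expect <- sqrt(2 / (7 * 7 * 3 + 7 * 7 * 128))
  expect_equal(stats::sd(m1$params[[2]]$W), sd_expect, tolerance = 0.05)
  expect_equal(mean(m1$params[[2]]$W), 0, tolerance = sd_expect / 10)
  expect_true(all(m1$params[[2]]$b == 0))
})

test_that("inconsistent batch-norm channels are a construction error", {
  bad <- cnn_spec(list(
    layer_input(c(8, 8, 2)), layer_conv(4, 3), layer_batch_norm(8),
    layer_relu(), layer_fully_connected(5), layer_softmax(),
    layer_classification()))
  expect_error(build_model(bad, seed = 1), "batch_norm")
})

test_that("analytic gradients agree with finite differences on a tiny net", {
  set.seed(42)
  m <- build_model(tiny_spec(), seed = 3)
  B <- 4
  x <- array(rnorm(8 * 8 * 2 * B), c(8, 8, 2, B))
  ycode <- c(1L, 3L, 5L, 2L)
  loss_fn <- function(mm) {
    fw <- sleepwave:::net_forward(mm, x, train = TRUE)
    sum(-log(fw$probs[cbind(seq_len(B), ycode)])) / B
  }
  fw <- sleepwave:::net_forward(m, x, train = TRUE)
  onehot <- matrix(0, B, 5)
  onehot[cbind(seq_len(B), ycode)] <- 1
  gr <- sleepwave:::net_backward(m, fw$cache, onehot, scale = B)
  eps <- 1e-6
  for (li in seq_along(m$params)) {
    if (is.null(m$params[[li]])) next
    for (nm in names(m$params[[li]])) {
      v <- m$params[[li]][[nm]]
      for (j in sample(length(v), min(5, length(v)))) {
        mp <- m; mp$params[[li]][[nm]][j] <- v[j] + eps
        mn <- m; mn$params[[li]][[nm]][j] <- v[j] - eps
        num <- (loss_fn(mp) - loss_fn(mn)) / (2 * eps)
        expect_equal(gr[[li]][[nm]][j], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("probabilities are normalized and ties break to the lowest index", {
  m <- build_model(default_model_spec(), seed = 7)
  set.seed(1)
  imgs <- lapply(1:3, function(i) array(runif(64 * 64 * 3), c(64, 64, 3)))
  p <- predict_proba(m, imgs)
  expect_equal(dim(p), c(3L, 5L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)

  # zero-initialized final layer: exactly uniform probabilities
  m0 <- m
  m0$params[[17]]$W[] <- 0
  m0$params[[17]]$b[] <- 0
  p0 <- predict_proba(m0, imgs)
  expect_equal(as.vector(p0), rep(0.2, 15))
  pred <- classify_stages(m0, imgs)
  expect_equal(as.character(pred), rep("W", 3))   # lowest index on ties

  expect_error(predict_proba(m, array(0, c(32, 32, 3))), "64x64x3")
})

test_that("the model can overfit a small image set to 100% training accuracy", {
  imgs <- small_image_set()           # 30 images, 6 per class
  sub <- imgs[seq_len(min(32, nrow(imgs))), ]
  m <- build_model(default_model_spec(), seed = 2)
  cfg <- train_config(batch_size = 16, max_epochs = 12, seed = 2,
                      validation_frequency = 0,
                      early_stop_val_acc = 1)
  m <- train_cnn(m, sub, val_set = sub, cfg = cfg)
  acc <- mean(as.character(classify_stages(m, sub)) ==
                as.character(sub$stage))
  expect_equal(acc, 1)
  # optimization sanity: final loss below first-iteration loss
  expect_lt(utils::tail(m$history$loss, 1), m$history$loss[1])
})

test_that("training histories are reproducible under identical seeds", {
  imgs <- small_image_set()
  sub <- imgs[1:10, ]
  cfg <- train_config(batch_size = 5, max_epochs = 1, seed = 9,
                      validation_frequency = 0)
  m1 <- train_cnn(build_model(tiny64_spec(), seed = 4), sub, cfg = cfg)
  m2 <- train_cnn(build_model(tiny64_spec(), seed = 4), sub, cfg = cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params, m2$params)
})

test_that("shuffling the training order changes history but not the reachable accuracy", {
  imgs <- small_image_set()
  fit <- function(shuffle_seed) {
    cfg <- train_config(batch_size = 10, max_epochs = 6,
                        seed = shuffle_seed, validation_frequency = 0,
                        early_stop_val_acc = 1)
    m <- train_cnn(build_model(tiny64_spec(), seed = 8), imgs,
                   val_set = imgs, cfg = cfg)
    list(acc = mean(as.character(classify_stages(m, imgs)) ==
                      as.character(imgs$stage)),
         history = m$history$loss)
  }
  a <- fit(101)
  b <- fit(202)
  expect_false(identical(a$history, b$history))
  expect_gte(a$acc, 0.9)
  expect_gte(b$acc, 0.9)
})

test_that("checkpoints round-trip the trained model", {
  imgs <- small_image_set()
  m <- build_model(tiny64_spec(), seed = 5)
  cfg <- train_config(batch_size = 8, max_epochs = 1, seed = 5,
                      validation_frequency = 0)
  m <- train_cnn(m, imgs[1:8, ], cfg = cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_equal(predict_proba(back, imgs[1:3, ]),
               predict_proba(m, imgs[1:3, ]))
  saveRDS(list(a = 1), path)
  expect_error(load_checkpoint(path), "checkpoint")
})
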