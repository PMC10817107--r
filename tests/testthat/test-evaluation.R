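test_that("split ratios must be valid", {
  expect_error(split_spec(0.5, 0.5, 0.5), "sum to 1")
  expect_error(split_spec(1, 0.5, -0.5), "in \\(0, 1\\)")
})

test_that("stratified 70/15/15 split partitions exactly", {
  d <- tibble::tibble(id = 1:1000,
                      stage = rep(stage_levels(), each = 200))
  parts <- split_dataset(d, split_spec(seed = 3))
  expect_equal(vapply(parts, nrow, integer(1)),
               c(train = 700L, val = 150L, test = 150L))
  ids <- sort(unname(unlist(lapply(parts, `[[`, "id"))))
  expect_equal(ids, 1:1000)                       # union = input
  expect_equal(anyDuplicated(unlist(lapply(parts, `[[`, "id"))), 0L)
  # per-class proportions preserved within one item
  for (p in parts) expect_true(all(abs(table(p$stage) - nrow(p) / 5) <= 1))

  parts2 <- split_dataset(d, split_spec(seed = 3))
  expect_identical(parts$train$id, parts2$train$id)
  parts3 <- split_dataset(d, split_spec(seed = 4))
  expect_false(identical(parts$train$id, parts3$train$id))
})

test_that("unbalanced and tiny datasets still partition cleanly", {
  d <- tibble::tibble(stage = c(rep("W", 11), rep("N3", 7), rep("REM", 3)))
  parts <- split_dataset(d, split_spec(seed = 1))
  expect_equal(sum(vapply(parts, nrow, integer(1))), 21L)
  d_empty_class <- tibble::tibble(stage = character(0))
  expect_error(split_dataset(d_empty_class), "no items")
})

test_that("confusion matrix tallies counts in canonical order", {
  cm <- confusion(rep(stage_levels(), each = 2), rep(stage_levels(), each = 2))
  expect_equal(diag(unclass(cm)), stats::setNames(rep(2L, 5), stage_levels()))
  expect_equal(sum(cm), 10)

  cm2 <- confusion(c("W", "N1"), c("N1", "N1"))
  expect_equal(unclass(cm2)["W", "N1"], 1L)
  expect_equal(unclass(cm2)["N1", "N1"], 1L)
  expect_equal(sum(cm2), 2)

  cm0 <- confusion(character(0), character(0))
  expect_true(all(unclass(cm0) == 0))

  expect_error(confusion("W", c("W", "N1")), "equal length")
})

test_that("metrics match hand-computed one-vs-rest values", {
  m <- matrix(c(8, 1, 1,
                0, 9, 1,
                1, 0, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  met <- metrics_from_confusion(m)
  expect_equal(attr(met, "overall_accuracy"), 26 / 30)
  expect_equal(met$sensitivity[1], 8 / 10)
  expect_equal(met$precision[1], 8 / 9)
  expect_equal(met$specificity[1], 19 / 20)
  expect_equal(met$f1[1], 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  expect_equal(met$binary_accuracy[1], (8 + 19) / 30)
  expect_equal(met$recall_as_accuracy, met$sensitivity)

  perfect <- metrics_from_confusion(diag(c(3, 4, 5, 2, 6)))
  expect_true(all(tibble::as_tibble(perfect)$sensitivity == 1))
  expect_equal(attr(perfect, "overall_accuracy"), 1)
  expect_equal(unname(attr(perfect, "macro")), rep(1, 5),
               ignore_attr = TRUE)

  expect_error(metrics_from_confusion(matrix(0, 5, 5)), "empty")
})

test_that("degenerate classes yield sentinels excluded from macro means", {
  cm <- confusion(c("W", "W", "N1"), c("W", "W", "W"))
  met <- metrics_from_confusion(cm)
  tab <- tibble::as_tibble(met)
  # N2/N3/REM absent from truth and prediction entirely
  absent <- tab$class %in% c("N2", "N3", "REM")
  expect_true(all(is.na(tab$sensitivity[absent])))
  expect_true(all(is.na(tab$precision[absent])))
  expect_true(all(tab$specificity[absent] == 1))
  expect_gt(attr(met, "n_excluded"), 0)
  expect_false(anyNA(attr(met, "macro")))
})

test_that("metric values always stay within [0, 1]", {
  set.seed(8)
  for (rep in 1:20) {
    truth <- sample(stage_levels(), 40, replace = TRUE)
    pred <- sample(stage_levels(), 40, replace = TRUE)
    tab <- tibble::as_tibble(metrics_from_confusion(confusion(truth, pred)))
    vals <- unlist(tab[, c("sensitivity", "specificity", "precision",
                           "f1", "binary_accuracy")])
    expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
  }
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney brute force", {
  brute <- function(scores, pos) {
    ps <- scores[pos]
    ns <- scores[!pos]
    cmp <- outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  # the documented 4-point toy: AUC = 0.75
  s <- c(0.1, 0.4, 0.35, 0.8)
  pos <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(sleepwave:::binary_auc(s, pos), 0.75)
  expect_equal(sleepwave:::binary_auc(s, pos), brute(s, pos))

  set.seed(12)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    scores <- round(runif(n), 2)       # heavy ties on purpose
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(sleepwave:::binary_auc(scores, pos), brute(scores, pos))
  }
})

test_that("one-vs-rest AUC handles separation, chance and missing classes", {
  truth <- c("W", "W", "N1", "N1")
  proba <- rbind(c(0.9, 0.1, 0, 0, 0), c(0.8, 0.2, 0, 0, 0),
                 c(0.2, 0.8, 0, 0, 0), c(0.1, 0.9, 0, 0, 0))
  colnames(proba) <- stage_levels()
  res <- auc_ovr(truth, proba)
  expect_equal(unname(res$per_class[c("W", "N1")]), c(1, 1))
  expect_true(all(is.na(res$per_class[c("N2", "N3", "REM")])))
  expect_equal(res$macro, 1)

  flat <- matrix(0.2, 4, 5, dimnames = list(NULL, stage_levels()))
  res2 <- auc_ovr(truth, flat)
  expect_equal(unname(res2$per_class[c("W", "N1")]), c(0.5, 0.5))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  truth <- sample(stage_levels(), 60, replace = TRUE)
  proba <- matrix(runif(300), 60, 5, dimnames = list(NULL, stage_levels()))
  proba <- proba / rowSums(proba)
  mine <- auc_ovr(truth, proba)
  for (cl in stage_levels()) {
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = factor(truth == cl, levels = c(FALSE, TRUE)),
      predictor = proba[, cl], quiet = TRUE, direction = "<")))
    expect_equal(unname(mine$per_class[cl]), ref, tolerance = 1e-12)
  }
})

test_that("k-fold evaluation partitions folds and aggregates mean ± sd", {
  d <- tibble::tibble(id = 1:100, stage = rep(stage_levels(), each = 20))
  majority_factory <- function(train_items) {
    lvl <- names(which.max(table(train_items$stage)))
    structure(list(lvl = lvl), class = "stub_majority")
  }
  assign("predict.stub_majority",
         function(object, newdata, type = "prob", ...) {
           p <- matrix(1e-6, nrow(newdata), 5,
                       dimnames = list(NULL, stage_levels()))
           p[, object$lvl] <- 1 - 4e-6
           p
         }, envir = globalenv())
  on.exit(rm("predict.stub_majority", envir = globalenv()), add = TRUE)

  cv <- kfold_evaluate(d, k = 10, model_factory = majority_factory, seed = 2)
  expect_equal(nrow(cv$folds), 10)
  expect_equal(sort(table(cv$assignments)), sort(rep(10L, 10)),
               ignore_attr = TRUE)
  # stratification: every fold holds 2 items of each class
  for (f in 1:10) {
    expect_true(all(table(d$stage[cv$assignments == f]) == 2))
  }
  # constant per-fold metric: sd must be zero
  acc_row <- cv$summary[cv$summary$metric == "accuracy", ]
  expect_equal(acc_row$mean, 0.2)
  expect_equal(acc_row$sd, 0)

  expect_error(kfold_evaluate(d, k = 1, majority_factory), "k")
  expect_error(kfold_evaluate(d, k = 25, majority_factory),
               "smallest class")
})

test_that("2-fold toy cross-validation matches hand-enumerated metrics", {
  # 4 items, 2 classes; the stub predicts W always, so each fold scores
  # accuracy 1/2, and mean = 1/2 with sd = 0
  d <- tibble::tibble(stage = c("W", "W", "N1", "N1"))
  factory <- function(train_items) {
    structure(list(), class = "stub_w")
  }
  assign("predict.stub_w",
         function(object, newdata, type = "prob", ...) {
           p <- matrix(0, nrow(newdata), 5,
                       dimnames = list(NULL, stage_levels()))
           p[, "W"] <- 1
           p
         }, envir = globalenv())
  on.exit(rm("predict.stub_w", envir = globalenv()), add = TRUE)
  cv <- kfold_evaluate(d, k = 2, model_factory = factory, seed = 5)
  expect_equal(cv$folds$accuracy, c(0.5, 0.5))
  s <- cv$summary
  expect_equal(s$mean[s$metric == "accuracy"], 0.5)
  expect_equal(s$sd[s$metric == "accuracy"], 0)
})

test_that("micro identity holds on random confusion matrices", {
  set.seed(90)
  for (rep in 1:10) {
    truth <- sample(stage_levels(), 60, replace = TRUE)
    pred <- sample(stage_levels(), 60, replace = TRUE)
    cm <- confusion(truth, pred)
    met <- metrics_from_confusion(cm)
    expect_equal(attr(met, "overall_accuracy"),
                 sum(diag(unclass(cm))) / sum(cm))
  }
})
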