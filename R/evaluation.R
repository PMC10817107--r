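#' Train/validation/test split specification
#'
#' @param train,val,test Ratios in (0,1) summing to 1 (defaults 0.70,
#'   0.15, 0.15, the standard split of the methodology).
#' @param stratified Preserve per-class proportions (default TRUE).
#' @param seed Integer seed for the shuffling.
#' @return A `split_spec`.
#' @export
split_spec <- function(train = 0.70, val = 0.15, test = 0.15,
                       stratified = TRUE, seed = 1L) {
  r <- c(train = train, val = val, test = test)
  if (any(r <= 0) || any(r >= 1)) {
    stop("each ratio must lie in (0, 1)", call. = FALSE)
  }
  if (abs(sum(r) - 1) > 1e-9) {
    stop("ratios must sum to 1 (got ", sum(r), ")", call. = FALSE)
  }
  structure(list(ratios = r, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_spec")
}

# Allocate n items to the ratios with largest-remainder rounding so the
# totals are exact.
allocate_counts <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Partitions a labeled item table into three disjoint subsets covering
#' every row, preserving per-class proportions to within one item
#' (largest-remainder allocation within each class). Reproducible under
#' the spec's seed.
#'
#' @param items Data frame with a `stage` column.
#' @param spec A [split_spec()].
#' @return Named list of three tibbles: `train`, `val`, `test`.
#' @export
#' @examples
#' d <- tibble::tibble(stage = rep(stage_levels(), each = 20))
#' sapply(split_dataset(d, split_spec(seed = 7)), nrow)
split_dataset <- function(items, spec = split_spec()) {
  stopifnot(is.data.frame(items), "stage" %in% names(items))
  stage <- stage_factor(items$stage)
  set.seed(spec$seed)
  assign <- character(nrow(items))
  groups <- if (spec$stratified) split(seq_len(nrow(items)), stage, drop = TRUE)
            else list(all = seq_len(nrow(items)))
  if (spec$stratified && any(lengths(groups) == 0)) {
    stop("stratified split requires at least one item per class",
         call. = FALSE)
  }
  if (length(groups) == 0) stop("no items to split", call. = FALSE)
  for (g in groups) {
    g <- g[sample.int(length(g))]
    cnt <- allocate_counts(length(g), spec$ratios)
    assign[g] <- rep(c("train", "val", "test"), times = cnt)
  }
  lapply(stats::setNames(nm = c("train", "val", "test")), function(part) {
    tibble::as_tibble(items[assign == part, , drop = FALSE])
  })
}

#' Confusion matrix over the five sleep stages
#'
#' `counts[i, j]` tallies items whose true stage is `i` and predicted
#' stage is `j`, in the canonical stage order.
#'
#' @param true,pred Stage tokens or factors of equal length.
#' @return A `sleep_confusion`: 5 x 5 integer matrix with dimnames
#'   `true`/`predicted`.
#' @export
#' @examples
#' confusion(c("W", "N1"), c("N1", "N1"))
confusion <- function(true, pred) {
  true <- stage_factor(true)
  pred <- stage_factor(pred)
  if (length(true) != length(pred)) {
    stop("true and pred must have equal length", call. = FALSE)
  }
  m <- table(true = true, pred = pred)
  m <- matrix(as.integer(m), nrow = length(stage_levels()),
              dimnames = list(true = stage_levels(),
                              predicted = stage_levels()))
  structure(m, class = c("sleep_confusion", "matrix"))
}

#' @export
print.sleep_confusion <- function(x, ...) {
  cat("<sleep_confusion> rows = true, cols = predicted\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class and macro metrics from a confusion matrix
#'
#' One-vs-rest tallies per class k (TP, FP, FN, TN) give sensitivity
#' (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, F1 `2PR/(P+R)` and binary accuracy `(TP+TN)/total`;
#' overall accuracy is `trace/total`. Zero-denominator cases yield `NA`
#' and are excluded from the macro averages (the number of excluded
#' classes is reported). Note some published tables label per-class
#' recall as "accuracy"; both are returned here, clearly named.
#'
#' @param cm A [confusion()] matrix (any square integer matrix with
#'   dimnames works).
#' @return A `stage_metrics` object: tibble of per-class rows with
#'   attributes `overall_accuracy`, `macro` (named vector) and
#'   `n_excluded`.
#' @export
metrics_from_confusion <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("cm must be a square matrix", call. = FALSE)
  }
  total <- sum(m)
  if (total <= 0) stop("confusion matrix is empty", call. = FALSE)
  classes <- rownames(m) %||% as.character(seq_len(nrow(m)))
  tp <- unname(diag(m))
  fn <- unname(rowSums(m)) - tp
  fp <- unname(colSums(m)) - tp
  tn <- total - tp - fn - fp
  div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- ifelse(!is.na(prec) & !is.na(sens) & (prec + sens) > 0,
               2 * prec * sens / (prec + sens), NA_real_)
  bin_acc <- (tp + tn) / total
  tab <- tibble::tibble(
    class = classes, tp = as.numeric(tp), fp = as.numeric(fp),
    fn = as.numeric(fn), tn = as.numeric(tn),
    sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
    binary_accuracy = bin_acc, recall_as_accuracy = sens
  )
  macro_of <- function(v) mean(v, na.rm = TRUE)
  macro <- c(sensitivity = macro_of(sens), specificity = macro_of(spec),
             precision = macro_of(prec), f1 = macro_of(f1),
             binary_accuracy = macro_of(bin_acc))
  structure(tab, class = c("stage_metrics", class(tab)),
            overall_accuracy = sum(tp) / total,
            macro = macro,
            n_excluded = sum(is.na(sens) | is.na(prec)))
}

#' @export
print.stage_metrics <- function(x, ...) {
  cat(sprintf("<stage_metrics> overall accuracy %.4f, macro F1 %s (%d class(es) excluded)\n",
              attr(x, "overall_accuracy"),
              formatC(attr(x, "macro")[["f1"]], digits = 4, format = "f"),
              attr(x, "n_excluded")))
  NextMethod()
}

#' One-vs-rest ROC AUC
#'
#' Per-class area under the ROC curve by the trapezoidal rule over all
#' score thresholds (equivalently the tie-aware Mann-Whitney statistic),
#' treating each class in turn as positive; the macro value is the
#' unweighted mean over classes with both positive and negative examples
#' (classes without either yield `NA`).
#'
#' @param true Stage tokens or factor.
#' @param proba Matrix of per-class scores, columns in canonical stage
#'   order (column names used when present).
#' @return List with `per_class` (named numeric) and `macro`.
#' @export
auc_ovr <- function(true, proba) {
  true <- stage_factor(true)
  proba <- as.matrix(proba)
  if (nrow(proba) != length(true)) {
    stop("proba must have one row per item", call. = FALSE)
  }
  classes <- colnames(proba) %||% stage_levels()[seq_len(ncol(proba))]
  per <- vapply(seq_along(classes), function(k) {
    pos <- as.character(true) == classes[k]
    binary_auc(proba[, k], pos)
  }, numeric(1))
  names(per) <- classes
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

# Trapezoidal ROC AUC for one binary problem. Sweeping the threshold over
# the distinct scores traces the ROC; trapezoids handle ties (half
# credit), so the value equals the Mann-Whitney U statistic normalized by
# n_pos * n_neg.
binary_auc <- function(scores, positive) {
  np <- sum(positive)
  nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positive[ord]
  # cumulative TP/FP at each distinct threshold
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Stratified k-fold cross-validation
#'
#' Splits the items into k disjoint stratified test folds; for every
#' fold, trains a fresh model on the remaining items via `model_factory`
#' and evaluates on the held-out fold. Metrics are aggregated as mean and
#' sample standard deviation (n-1 denominator) across folds.
#'
#' @param items Data frame with `stage` plus whatever the factory needs.
#' @param k Number of folds (>= 2, at most the smallest class count).
#' @param model_factory `function(train_items)` returning an object with a
#'   `predict(object, newdata, type = "prob")` method (a `sleep_cnn`
#'   works as is).
#' @param seed Integer seed for fold assignment.
#' @return A `cv_result`: list with `folds` (per-fold metric tibble),
#'   `summary` (mean/sd per metric) and `assignments`.
#' @export
kfold_evaluate <- function(items, k = 10, model_factory, seed = 1L) {
  stopifnot(is.data.frame(items), "stage" %in% names(items))
  stage <- stage_factor(items$stage)
  counts <- table(droplevels(stage))
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (any(counts < k)) {
    stop("k = ", k, " exceeds the smallest class count (",
         min(counts), ")", call. = FALSE)
  }
  set.seed(as.integer(seed))
  fold <- integer(nrow(items))
  for (g in split(seq_len(nrow(items)), stage, drop = TRUE)) {
    g <- g[sample.int(length(g))]
    fold[g] <- rep_len(seq_len(k), length(g))
  }
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    train_items <- tibble::as_tibble(items[fold != f, , drop = FALSE])
    test_items <- tibble::as_tibble(items[fold == f, , drop = FALSE])
    model <- model_factory(train_items)
    proba <- stats::predict(model, test_items, type = "prob")
    pred <- stage_levels()[max.col(as.matrix(proba), ties.method = "first")]
    met <- metrics_from_confusion(confusion(test_items$stage, pred))
    auc <- auc_ovr(test_items$stage, proba)
    macro <- attr(met, "macro")
    fold_rows[[f]] <- tibble::tibble(
      fold = f,
      accuracy = attr(met, "overall_accuracy"),
      sensitivity = macro[["sensitivity"]],
      specificity = macro[["specificity"]],
      precision = macro[["precision"]],
      f1 = macro[["f1"]],
      auc = auc$macro
    )
  }
  folds <- dplyr::bind_rows(fold_rows)
  metric_cols <- setdiff(names(folds), "fold")
  summary <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(folds[metric_cols], mean, numeric(1), na.rm = TRUE,
                  USE.NAMES = FALSE),
    sd = vapply(folds[metric_cols], stats::sd, numeric(1),
                USE.NAMES = FALSE)
  )
  structure(list(folds = folds, summary = summary, assignments = fold,
                 k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold cross-validation\n", x$k))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.4f ± %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
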