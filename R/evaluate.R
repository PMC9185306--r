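#' Stratified train / validation / test split
#'
#' Per class: shuffle with the seed, take `round(n * test_frac)` rows for
#' the test set, then `round` of the remainder times `val_frac` for
#' validation, and the rest for training (round-half-up), so 1000 images
#' per class reproduce the canonical 640/160/200 bookkeeping exactly. The
#' three index sets are disjoint and exhaustive.
#'
#' @param labels class label per item (vector or factor).
#' @param test_frac test share of each class.
#' @param val_frac validation share of the non-test remainder.
#' @param seed RNG seed for the per-class shuffles.
#' @param min_per_class smallest admissible class size.
#' @return a `split_result` list with integer index vectors `train`,
#'   `validation`, `test` plus the seed and fractions used.
#' @export
split_dataset <- function(labels, test_frac = 0.2, val_frac = 0.2, seed = 1L,
                          min_per_class = 5L) {
  labels <- factor(labels)
  counts <- table(labels)
  if (any(counts < min_per_class)) {
    stop(sprintf("every class needs at least %d items (smallest has %d)",
                 min_per_class, min(counts)), call. = FALSE)
  }
  train <- validation <- test <- integer()
  for (k in levels(labels)) {
    ik <- which(labels == k)
    ik <- withr::with_seed(seed + match(k, levels(labels)), sample(ik))
    n <- length(ik)
    n_test <- round_half_up(n * test_frac)
    rem <- n - n_test
    n_val <- round_half_up(rem * val_frac)
    test <- c(test, ik[seq_len(n_test)])
    validation <- c(validation, ik[n_test + seq_len(n_val)])
    train <- c(train, ik[-(seq_len(n_test + n_val))])
  }
  structure(list(train = sort(train), validation = sort(validation),
                 test = sort(test), seed = as.integer(seed),
                 fractions = c(test = test_frac, val = val_frac)),
            class = "split_result")
}

# ---- image-level augmentation -------------------------------------------

rot90cw <- function(px) {
  if (length(dim(px)) == 3L) {
    out <- aperm(px, c(2, 1, 3))
    out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
  } else {
    t(px)[, rev(seq_len(nrow(px))), drop = FALSE][, , drop = TRUE]
  }
}

flip_h <- function(px) {
  if (length(dim(px)) == 3L) px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  else px[, rev(seq_len(ncol(px))), drop = FALSE]
}

flip_v <- function(px) {
  if (length(dim(px)) == 3L) px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
  else px[rev(seq_len(nrow(px))), , drop = FALSE]
}

# shift with replicate fill
translate_px <- function(px, dr, dc) {
  d <- dim(px)
  ri <- pmin(pmax(seq_len(d[1]) - dr, 1L), d[1])
  ci <- pmin(pmax(seq_len(d[2]) - dc, 1L), d[2])
  if (length(d) == 3L) px[ri, ci, , drop = FALSE] else px[ri, ci, drop = FALSE]
}

# centre zoom by nearest-neighbour resampling
zoom_px <- function(px, factor) {
  d <- dim(px)
  ri <- pmin(pmax(round((seq_len(d[1]) - (d[1] + 1) / 2) / factor +
                          (d[1] + 1) / 2), 1L), d[1])
  ci <- pmin(pmax(round((seq_len(d[2]) - (d[2] + 1) / 2) / factor +
                          (d[2] + 1) / 2), 1L), d[2])
  if (length(d) == 3L) px[ri, ci, , drop = FALSE] else px[ri, ci, drop = FALSE]
}

#' Augment a training set eightfold
#'
#' Each image yields itself plus seven label-preserving transforms:
#' horizontal flip, vertical flip, the three square rotations (90/180/270
#' degrees), a seeded translation of at most 10% of each dimension, and a
#' seeded zoom in `[0.9, 1.1]`. 640 training images per class become 5120.
#' Only the training split may be augmented; passing a dataset whose
#' `role` is `"validation"` or `"test"` is an error.
#'
#' @param ds a labelled dataset: `list(items = list of pixel arrays,
#'   labels = , role = "train")` (as produced by [generate_dataset] and
#'   subset to the training indices).
#' @param seed RNG seed for the translation / zoom magnitudes.
#' @return the augmented dataset, `8 *` the item count, `role = "train"`.
#' @export
augment_dataset <- function(ds, seed = 1L) {
  stopifnot(is.list(ds$items), length(ds$items) == length(ds$labels))
  role <- if (is.null(ds$role)) "train" else ds$role
  if (!identical(role, "train")) {
    stop("augmentation is restricted to the training split", call. = FALSE)
  }
  n <- length(ds$items)
  pars <- withr::with_seed(seed, data.frame(
    dr = stats::runif(n, -0.1, 0.1), dc = stats::runif(n, -0.1, 0.1),
    zoom = stats::runif(n, 0.9, 1.1)))
  items <- vector("list", 8L * n)
  labels <- rep(ds$labels, each = 8L)
  for (i in seq_len(n)) {
    px <- unclass(ds$items[[i]])
    d <- dim(px)
    r90 <- rot90cw(px)
    items[(i - 1L) * 8L + 1:8] <- list(
      px, flip_h(px), flip_v(px), r90, rot90cw(r90), rot90cw(rot90cw(r90)),
      translate_px(px, round_half_up(pars$dr[i] * d[1]),
                   round_half_up(pars$dc[i] * d[2])),
      zoom_px(px, pars$zoom[i]))
  }
  list(items = items, labels = labels, classes = ds$classes, role = "train")
}

#' Multiclass confusion matrix
#'
#' `K x K` count matrix with rows = actual classes and columns = predicted
#' classes.
#'
#' @param actual,predicted equal-length label vectors.
#' @param classes the fixed class list; labels outside it are an error.
#' @return integer matrix with `dimnames = list(actual, predicted)`.
#' @export
confusion <- function(actual, predicted, classes = NULL) {
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(c(as.character(actual),
                                                 as.character(predicted))))
  bad <- setdiff(unique(c(as.character(actual), as.character(predicted))),
                 classes)
  if (length(bad)) {
    stop(sprintf("labels outside the class list: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  a <- factor(actual, levels = classes)
  p <- factor(predicted, levels = classes)
  m <- table(actual = a, predicted = p)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(actual = classes, predicted = classes))
}

# one 0/0-guarded percentage; empty denominators score 100 (nothing to miss)
rate_pct <- function(num, den) if (den == 0) 100 else 100 * num / den

#' Per-class and overall metrics from a confusion matrix
#'
#' Each class is scored one-vs-rest: with its TP/TN/FP/FN counts,
#' `accuracy = (TP + TN) / total * 100`,
#' `precision = TP / (TP + FP) * 100`,
#' `sensitivity = TP / (TP + FN) * 100`,
#' `specificity = TN / (TN + FP) * 100`. Macro values are unweighted class
#' means; the overall accuracy is `trace / total * 100`. Rates with an
#' empty denominator (no positives predicted, or no negatives present) are
#' reported as 100, since the error set they measure is empty.
#'
#' @param cm a [confusion] matrix.
#' @return a `metrics_report`: `per_class` data frame, `macro` named
#'   vector, `overall_accuracy`.
#' @export
cm_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(cm)
  per <- do.call(rbind, lapply(seq_along(classes), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    data.frame(class = classes[k],
               accuracy = 100 * (tp + tn) / total,
               precision = rate_pct(tp, tp + fp),
               sensitivity = rate_pct(tp, tp + fn),
               specificity = rate_pct(tn, tn + fp))
  }))
  macro <- vapply(per[, -1], mean, numeric(1))
  structure(list(per_class = per, macro = macro,
                 overall_accuracy = 100 * sum(diag(cm)) / total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics (%):\n")
  print(cbind(x$per_class[1],
              round(as.matrix(x$per_class[, -1]), 1)), row.names = FALSE)
  cat(sprintf("Macro: %s\n",
              paste(sprintf("%s %.1f", names(x$macro), x$macro),
                    collapse = ", ")))
  cat(sprintf("Overall accuracy: %.1f%%\n", x$overall_accuracy))
  invisible(x)
}

#' Size-weighted overall accuracy from per-class accuracies
#'
#' Aggregates a row of per-class diagnostic accuracies into the single
#' overall figure, weighting each class by its test-set size; reported to
#' one decimal.
#'
#' @param per_class_acc per-class accuracies in percent.
#' @param class_sizes test-set size per class.
#' @return scalar percent, rounded to 1 decimal.
#' @export
overall_accuracy <- function(per_class_acc, class_sizes) {
  if (length(per_class_acc) != length(class_sizes)) {
    stop("`per_class_acc` and `class_sizes` must have equal length",
         call. = FALSE)
  }
  stopifnot(all(class_sizes > 0))
  round(sum(per_class_acc * class_sizes) / sum(class_sizes), 1)
}

# AUC of one score column vs binary truth, by threshold sweep + trapezoid
auc_binary <- function(scores, positive) {
  if (!any(positive) || all(positive)) {
    stop("AUC undefined: need at least one positive and one negative",
         call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[positive] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!positive] >= t), numeric(1))
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' One-vs-rest ROC area under the curve
#'
#' Per class, the ROC curve is swept over every score threshold and the
#' area computed by the trapezoid rule (ties therefore count one half, the
#' rank-statistic convention); reported in percent, with the macro value
#' the unweighted class mean.
#'
#' @param prob score/probability matrix, one column per class (named).
#' @param actual true labels.
#' @return list with `per_class` named vector and `macro`, both in percent.
#' @export
roc_auc <- function(prob, actual) {
  prob <- as.matrix(prob)
  classes <- colnames(prob)
  if (is.null(classes)) stop("probability columns must be named by class",
                             call. = FALSE)
  actual <- as.character(actual)
  per <- vapply(classes, function(k) {
    100 * auc_binary(prob[, k], actual == k)
  }, numeric(1))
  list(per_class = per, macro = mean(per))
}

#' Pixel-level scores of a predicted mask against ground truth
#'
#' TP/TN/FP/FN are counted pixelwise; accuracy, precision and recall follow
#' the usual one-vs-rest formulas and the overlap is summarized by
#' `Dice = 2 TP / (2 TP + FP + FN)`. All values in percent.
#'
#' @param pred,truth binary masks of identical shape.
#' @return named numeric: `accuracy`, `precision`, `recall`, `dice`.
#' @export
mask_scores <- function(pred, truth) {
  p <- as.matrix(pred) > 0
  t <- as.matrix(truth) > 0
  if (!all(dim(p) == dim(t))) stop("mask shapes differ", call. = FALSE)
  tp <- sum(p & t); tn <- sum(!p & !t)
  fp <- sum(p & !t); fn <- sum(!p & t)
  c(accuracy = 100 * (tp + tn) / length(p),
    precision = if (tp + fp == 0) 0 else 100 * tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else 100 * tp / (tp + fn),
    dice = if (2 * tp + fp + fn == 0) 100 else 100 * 2 * tp / (2 * tp + fp + fn))
}
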