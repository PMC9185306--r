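test_that("stratified splitting reproduces the canonical 640/160/200 counts", {
  labels <- rep(phantom_classes(), each = 1000)
  sp <- split_dataset(labels, seed = 1)
  for (k in phantom_classes()) {
    expect_equal(sum(labels[sp$train] == k), 640)
    expect_equal(sum(labels[sp$validation] == k), 160)
    expect_equal(sum(labels[sp$test] == k), 200)
  }
})

test_that("splits partition the data and are seed-deterministic", {
  set.seed(71)
  for (i in 1:5) {
    n <- sample(30:200, 3)
    labels <- rep(c("a", "b", "c"), n)
    sp <- split_dataset(labels, seed = i)
    all_idx <- c(sp$train, sp$validation, sp$test)
    expect_setequal(all_idx, seq_along(labels))
    expect_equal(length(all_idx), length(labels))  # disjoint + exhaustive
    sp2 <- split_dataset(labels, seed = i)
    expect_identical(sp, sp2)
  }
  expect_error(split_dataset(c("a", "a", "b")), "at least")
})

test_that("per-class split counts depend only on class size and fractions", {
  a <- split_dataset(rep(c("x", "y"), c(57, 91)), seed = 3)
  b <- split_dataset(rep(c("q", "z"), c(57, 91)), seed = 3)
  count_of <- function(sp, labels) {
    sapply(list(sp$train, sp$validation, sp$test),
           function(ix) as.numeric(table(labels[ix])))
  }
  expect_equal(count_of(a, rep(c("x", "y"), c(57, 91))),
               count_of(b, rep(c("q", "z"), c(57, 91))))
})

test_that("augmentation produces exactly eight label-preserving copies", {
  set.seed(72)
  items <- lapply(1:3, function(i) array(runif(20 * 20 * 3, 0, 255),
                                         c(20, 20, 3)))
  ds <- list(items = items, labels = factor(c("a", "b", "a")),
             role = "train")
  aug <- augment_dataset(ds, seed = 1)
  expect_length(aug$items, 24)
  expect_equal(as.character(aug$labels),
               rep(c("a", "b", "a"), each = 8))
  # first copy of each image is the original
  expect_identical(aug$items[[1]], unclass(items[[1]]))
  expect_identical(aug$items[[9]], unclass(items[[2]]))

  ds$role <- "test"
  expect_error(augment_dataset(ds, seed = 1), "training")
})

test_that("confusion matrices tally rows-actual by columns-predicted", {
  cls <- c("a", "b", "c")
  perfect <- confusion(rep(cls, 4), rep(cls, 4), cls)
  expect_equal(diag(perfect), c(a = 4, b = 4, c = 4), ignore_attr = TRUE)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)

  actual <- c("a", "a", "a", "b", "b", "b", "c", "c", "c", "a")
  pred <- c("a", "b", "a", "b", "b", "c", "c", "a", "c", "a")
  cm <- confusion(actual, pred, cls)
  expect_equal(cm, oracle_confusion(actual, pred, cls), ignore_attr = TRUE)
  expect_equal(sum(cm), 10)

  set.seed(73)
  for (i in 1:5) {
    a <- sample(cls, 30, replace = TRUE)
    p <- sample(cls, 30, replace = TRUE)
    expect_equal(confusion(a, p, cls), oracle_confusion(a, p, cls),
                 ignore_attr = TRUE)
  }
  expect_error(confusion("a", "d", cls), "outside")
})

test_that("one-vs-rest metrics follow the TP/TN/FP/FN formulas", {
  perfect <- diag(40, 5)
  rownames(perfect) <- colnames(perfect) <- phantom_classes()
  rep5 <- cm_metrics(perfect)
  expect_true(all(as.matrix(rep5$per_class[, -1]) == 100))
  expect_equal(rep5$overall_accuracy, 100)

  cm <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  r <- cm_metrics(cm)
  expect_equal(r$overall_accuracy, 85)
  expect_equal(r$per_class$accuracy, c(85, 85))
  expect_equal(r$per_class$sensitivity[1], 80)
  expect_equal(r$per_class$precision[1], 100 * 8 / 9, tolerance = 1e-9)
  expect_equal(unname(r$macro["precision"]),
               mean(r$per_class$precision))
  expect_error(cm_metrics(matrix(0, 2, 2)), "empty")
})

test_that("overall accuracy aggregates per-class accuracies by test size", {
  expect_equal(overall_accuracy(c(96.5, 98.5, 96.5, 96.5, 99),
                                rep(200, 5)), 97.4)
  expect_equal(overall_accuracy(c(98.5, 100, 100, 93.5, 91.5),
                                rep(200, 5)), 96.7)
  expect_equal(overall_accuracy(rep(93.7, 4), c(10, 20, 30, 40)), 93.7)
  expect_error(overall_accuracy(c(1, 2), 1), "equal length")
})

test_that("ROC areas match the rank-statistic oracle", {
  prob <- cbind(a = c(0.9, 0.8, 0.2, 0.1), b = c(0.1, 0.2, 0.8, 0.9))
  actual <- c("a", "a", "b", "b")
  r <- roc_auc(prob, actual)
  expect_equal(unname(r$per_class), c(100, 100))

  swapped <- prob[, c(2, 1)]
  colnames(swapped) <- c("a", "b")
  inverted <- roc_auc(swapped, actual)
  expect_equal(unname(inverted$per_class), c(0, 0))

  set.seed(74)
  for (i in 1:5) {
    scores <- round(runif(30), 2)           # rounding forces ties
    truth <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(truth) || all(truth)) next
    impl <- endodiag:::auc_binary(scores, truth)
    expect_equal(impl, oracle_auc(scores, truth), tolerance = 1e-9)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(impl, ref, tolerance = 1e-9)
    }
    # invariance under strictly monotone transforms
    expect_equal(endodiag:::auc_binary(exp(3 * scores), truth), impl,
                 tolerance = 1e-9)
  }
  expect_error(roc_auc(prob, c("a", "a", "a", "a")), "positive")
})

test_that("mask scoring counts pixels exactly", {
  m <- matrix(FALSE, 10, 10)
  a <- m; a[2:7, 2:7] <- TRUE
  expect_equal(unname(mask_scores(a, a)), rep(100, 4))

  b <- m; b[8:10, 8:10] <- TRUE
  s <- mask_scores(a, b)
  expect_equal(unname(s[c("precision", "recall", "dice")]), c(0, 0, 0))

  # half-overlapping rectangles, counted by hand
  p <- m; p[1:10, 1:6] <- TRUE              # 60 pixels
  t <- m; t[1:10, 4:9] <- TRUE              # 60 pixels, 30 shared
  s2 <- mask_scores(p, t)
  expect_equal(unname(s2["precision"]), 100 * 30 / 60)
  expect_equal(unname(s2["recall"]), 100 * 30 / 60)
  expect_equal(unname(s2["dice"]), 100 * 60 / 120)
  expect_equal(unname(s2["accuracy"]), 100 * (100 - 60) / 100)
  expect_error(mask_scores(a, matrix(FALSE, 5, 5)), "differ")
})
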