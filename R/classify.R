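#' Numerically stable softmax
#'
#' `y(x_i) = exp(x_i) / sum_j exp(x_j)`, computed after subtracting the
#' maximum logit so that magnitudes up to about 1e300 cannot overflow.
#'
#' @param logits numeric vector (or matrix: softmax per row).
#' @return probabilities of the same shape; each row sums to 1.
#' @export
softmax <- function(logits) {
  if (length(logits) == 0L) stop("empty logit vector", call. = FALSE)
  if (is.matrix(logits)) {
    z <- exp(logits - apply(logits, 1, max))
    return(z / rowSums(z))
  }
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Rectified linear unit
#'
#' Element-wise `max(0, x)`.
#'
#' @param x numeric vector/matrix.
#' @return same shape.
#' @export
relu <- function(x) pmax(x, 0)

#' Mean squared error
#'
#' `(1/n) * sum (actual_i - predicted_i)^2`; logged alongside cross-entropy
#' during network training.
#'
#' @param actual,predicted equal-length numeric vectors.
#' @return scalar.
#' @export
mse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  }
  stopifnot(length(actual) >= 1)
  mean((actual - predicted)^2)
}

#' Training configuration for the shallow network
#'
#' @param hidden hidden-layer width (one hidden layer of this many units).
#' @param max_epochs full-batch gradient-descent epoch cap.
#' @param lr learning rate (applied to standardized inputs).
#' @param momentum classical momentum coefficient.
#' @param patience early-stopping patience, in epochs without improvement of
#'   the validation cross-entropy.
#' @param val_frac fraction of the training rows carved out for validation
#'   when no explicit validation set is supplied.
#' @param seed RNG seed for weight initialization and the internal
#'   validation carve-out.
#' @return a `train_config` list.
#' @export
train_config <- function(hidden = 30L, max_epochs = 300L, lr = 0.2,
                         momentum = 0.9, patience = 25L, val_frac = 0.2,
                         seed = 1L) {
  stopifnot(max_epochs >= 1, patience >= 1, hidden >= 1, lr > 0)
  structure(list(hidden = as.integer(hidden),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 momentum = momentum, patience = as.integer(patience),
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "train_config")
}

check_training_input <- function(x, labels) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("feature matrix must be finite numeric", call. = FALSE)
  }
  if (length(labels) != nrow(x)) {
    stop("`labels` must have one entry per feature row", call. = FALSE)
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    stop("training needs at least 2 classes", call. = FALSE)
  }
  list(x = x, labels = labels)
}

#' Train a shallow feed-forward network
#'
#' One ReLU hidden layer (default 30 units), softmax output, cross-entropy
#' objective minimized by full-batch gradient descent with momentum, with
#' the mean squared error between one-hot targets and predicted
#' probabilities logged per epoch. Inputs are standardized internally.
#' Early stopping monitors the validation cross-entropy: training stops
#' once `patience` epochs pass without improvement and the weights of the
#' best validation epoch are restored. Fully deterministic given
#' `config$seed`.
#'
#' @param x numeric feature matrix, one row per sample.
#' @param labels class labels, one per row.
#' @param config a [train_config].
#' @param val optional validation set: `list(x = , labels = )`. When `NULL`
#'   a stratified `val_frac` share of the rows is held out.
#' @return an `mlp_model` with weights, the standardization, the class
#'   list, the per-epoch training log and the selected epoch.
#' @export
train_mlp <- function(x, labels, config = train_config(), val = NULL) {
  inp <- check_training_input(x, labels)
  x <- inp$x; labels <- inp$labels
  classes <- levels(labels)
  K <- length(classes)

  if (is.null(val)) {
    idx <- withr::with_seed(config$seed, {
      unlist(lapply(classes, function(k) {
        ik <- which(labels == k)
        sample(ik, max(1L, round_half_up(length(ik) * config$val_frac)))
      }), use.names = FALSE)
    })
    val <- list(x = x[idx, , drop = FALSE], labels = labels[idx])
    x <- x[-idx, , drop = FALSE]
    labels <- labels[-idx]
  }
  vx <- as.matrix(val$x)
  vlab <- factor(val$labels, levels = classes)

  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  vs <- sweep(sweep(vx, 2, center), 2, scale, "/")

  n <- nrow(xs); d <- ncol(xs); hsz <- config$hidden
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(labels))] <- 1
  Yv <- matrix(0, nrow(vs), K)
  Yv[cbind(seq_len(nrow(vs)), as.integer(vlab))] <- 1

  w <- withr::with_seed(config$seed, list(
    W1 = matrix(stats::rnorm(d * hsz), d, hsz) * sqrt(2 / d),
    b1 = rep(0, hsz),
    W2 = matrix(stats::rnorm(hsz * K), hsz, K) * sqrt(2 / hsz),
    b2 = rep(0, K)))
  vel <- lapply(w, function(m) m * 0)

  forward <- function(xm, w) {
    H <- relu(sweep(xm %*% w$W1, 2, w$b1, "+"))
    P <- softmax(sweep(H %*% w$W2, 2, w$b2, "+"))
    list(H = H, P = P)
  }
  ce <- function(P, Y) -mean(log(pmax(rowSums(P * Y), 1e-300)))

  best <- list(epoch = 0L, val = Inf, w = w)
  log_df <- data.frame(epoch = integer(), train_ce = numeric(),
                       val_ce = numeric(), train_mse = numeric())
  for (epoch in seq_len(config$max_epochs)) {
    fw <- forward(xs, w)
    G <- (fw$P - Y) / n                       # d CE / d logits
    gW2 <- t(fw$H) %*% G
    gb2 <- colSums(G)
    Gh <- (G %*% t(w$W2)) * (fw$H > 0)
    gW1 <- t(xs) %*% Gh
    gb1 <- colSums(Gh)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (nm in names(w)) {
      vel[[nm]] <- config$momentum * vel[[nm]] - config$lr * grads[[nm]]
      w[[nm]] <- w[[nm]] + vel[[nm]]
    }
    fv <- forward(vs, w)
    tr <- forward(xs, w)
    log_df <- rbind(log_df, data.frame(
      epoch = epoch, train_ce = ce(tr$P, Y), val_ce = ce(fv$P, Yv),
      train_mse = mse(as.numeric(Y), as.numeric(tr$P))))
    if (log_df$val_ce[epoch] < best$val) {
      best <- list(epoch = epoch, val = log_df$val_ce[epoch], w = w)
    }
    if (epoch - best$epoch >= config$patience) break
  }

  structure(list(W1 = best$w$W1, b1 = best$w$b1, W2 = best$w$W2,
                 b2 = best$w$b2, center = center, scale = scale,
                 classes = classes, log = log_df, best_epoch = best$epoch,
                 config = config),
            class = "mlp_model")
}

#' Predict classes (and probabilities) from a trained model
#'
#' @param object an `mlp_model`.
#' @param newdata feature matrix with the model's input width.
#' @param ... unused.
#' @return `list(class = factor, prob = matrix)`; probability rows sum
#'   to 1. An empty input yields empty predictions.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) > 0 && ncol(newdata) != length(object$center)) {
    stop(sprintf("feature width %d does not match model input width %d",
                 ncol(newdata), length(object$center)), call. = FALSE)
  }
  if (nrow(newdata) == 0L) {
    return(list(class = factor(character(), levels = object$classes),
                prob = matrix(numeric(), 0, length(object$classes),
                              dimnames = list(NULL, object$classes))))
  }
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  H <- relu(sweep(xs %*% object$W1, 2, object$b1, "+"))
  P <- softmax(sweep(H %*% object$W2, 2, object$b2, "+"))
  colnames(P) <- object$classes
  cls <- factor(object$classes[max.col(P, ties.method = "first")],
                levels = object$classes)
  list(class = cls, prob = P)
}

#' Train a multiclass support vector machine
#'
#' One-vs-one margin classifier on standardized features (linear kernel,
#' `C = 1` by default), intended for classifying deep feature maps in place
#' of a network's dense head. Backed by the reference libsvm
#' implementation.
#'
#' @param x numeric feature matrix.
#' @param labels class labels, one per row.
#' @param cost soft-margin constant C.
#' @param kernel kernel name passed through (`"linear"` default).
#' @param seed RNG seed (the linear solver is deterministic; the seed fixes
#'   any randomized internals).
#' @return an `svm_model` wrapper.
#' @export
train_svm <- function(x, labels, cost = 1, kernel = "linear", seed = 1L) {
  inp <- check_training_input(x, labels)
  fit <- withr::with_seed(seed,
    e1071::svm(inp$x, inp$labels, kernel = kernel, cost = cost,
               scale = apply(inp$x, 2, stats::sd) > 0))
  structure(list(fit = fit, classes = levels(inp$labels),
                 width = ncol(inp$x)),
            class = "svm_model")
}

#' @rdname train_svm
#' @param object an `svm_model`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) {
    return(list(class = factor(character(), levels = object$classes)))
  }
  if (ncol(newdata) != object$width) {
    stop(sprintf("feature width %d does not match model input width %d",
                 ncol(newdata), object$width), call. = FALSE)
  }
  list(class = factor(as.character(stats::predict(object$fit, newdata)),
                      levels = object$classes))
}

#' Serialize / restore a trained network as portable JSON
#'
#' The manifest stores layer shapes, classes, the input standardization and
#' flat weight payloads, so a model can be moved between machines without
#' binary formats.
#'
#' @param model an `mlp_model`.
#' @param path output (input) path.
#' @export
write_mlp <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(type = "mlp", classes = model$classes,
              dims = c(nrow(model$W1), ncol(model$W1), ncol(model$W2)),
              W1 = as.numeric(model$W1), b1 = model$b1,
              W2 = as.numeric(model$W2), b2 = model$b2,
              center = as.numeric(model$center),
              scale = as.numeric(model$scale),
              best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$dims
  structure(list(W1 = matrix(obj$W1, d[1], d[2]), b1 = obj$b1,
                 W2 = matrix(obj$W2, d[2], d[3]), b2 = obj$b2,
                 center = obj$center, scale = obj$scale,
                 classes = obj$classes, log = NULL,
                 best_epoch = obj$best_epoch, config = NULL),
            class = "mlp_model")
}
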