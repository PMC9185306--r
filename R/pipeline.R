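#' Extract the handcrafted (and optionally hybrid) feature table
#'
#' Per image: the frame is [enhance]d and the texture blocks (LBP,
#' co-occurrence statistics) are computed from the enhanced plane, the
#' colour block (FCH) from the original RGB pixels, optionally restricted
#' to a lesion mask; blocks are fused in the order `lbp, glcm, fch`
#' (with a leading `deep` block when an extractor is supplied).
#'
#' @param items list of [rgb_image]s / `H x W x 3` arrays.
#' @param masks optional list of binary masks (entries may be `NULL` for
#'   whole-frame extraction).
#' @param blocks character subset of `c("lbp", "glcm", "fch")`.
#' @param extractor optional `feature_extractor` adding a `deep` block.
#' @param lbp_bins,glcm_levels descriptor parameters.
#' @return numeric matrix, one row per image, with a `blocks` attribute
#'   naming each column's origin.
#' @export
extract_feature_table <- function(items, masks = NULL,
                                  blocks = c("lbp", "glcm", "fch"),
                                  extractor = NULL, lbp_bins = 203L,
                                  glcm_levels = 32L) {
  blocks <- match.arg(blocks, c("lbp", "glcm", "fch"), several.ok = TRUE)
  rows <- lapply(seq_along(items), function(i) {
    img <- items[[i]]
    msk <- if (is.null(masks)) NULL else masks[[i]]
    enh <- enhance(img)
    roi_gray <- make_roi(enh, msk)
    parts <- list()
    if (!is.null(extractor)) parts$deep <- deep_extract(img, extractor)
    if ("lbp" %in% blocks) {
      parts$lbp <- lbp_features(roi_gray, bins = lbp_bins)
    }
    if ("glcm" %in% blocks) {
      parts$glcm <- glcm_features(roi_gray, n_levels = glcm_levels)
    }
    if ("fch" %in% blocks) {
      parts$fch <- fch_features(make_roi(img, msk))
    }
    fuse_features(parts)
  })
  out <- do.call(rbind, lapply(rows, as.numeric))
  colnames(out) <- names(rows[[1]])
  attr(out, "blocks") <- attr(rows[[1]], "blocks")
  out
}

#' Write / read a feature table as CSV
#'
#' One row per image; descriptor columns are named `<block>_<index>`, with
#' `image_id` and `label` columns alongside.
#'
#' @param features feature matrix from [extract_feature_table].
#' @param labels class label per row.
#' @param path file path.
#' @param image_id optional identifiers (defaults to row numbers).
#' @export
write_feature_csv <- function(features, labels, path, image_id = NULL) {
  if (is.null(image_id)) image_id <- seq_len(nrow(features))
  df <- data.frame(image_id = image_id, label = as.character(labels),
                   as.data.frame(features, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @return `read_feature_csv`: `list(features = matrix, labels = factor,
#'   image_id = )`.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  feat <- as.matrix(df[, setdiff(names(df), c("image_id", "label")),
                       drop = FALSE])
  list(features = feat, labels = factor(df$label), image_id = df$image_id)
}

#' Run the full phantom study end to end
#'
#' Generates the balanced 5-class phantom dataset, extracts the
#' 232-dimensional handcrafted descriptor from every (enhanced) frame,
#' splits it stratified into train/validation/test, trains the shallow
#' network with early stopping on the validation split, and scores the
#' held-out test set.
#'
#' @param n_per_class phantoms per class.
#' @param seed master seed driving generation, splitting and training.
#' @param size phantom side length.
#' @param noise_sd phantom noise sigma.
#' @param config a [train_config] (its seed is overridden by `seed`).
#' @param use_masks extract features from ground-truth lesion ROIs where
#'   the class has one (`FALSE` = whole-frame extraction, the default).
#' @return list with `accuracy` (test fraction correct), `cm`, `metrics`,
#'   `auc`, `model`, `split`, `labels`, `features`.
#' @export
phantom_experiment <- function(n_per_class = 100L, seed = 1L, size = 128L,
                               noise_sd = 5, config = train_config(),
                               use_masks = FALSE) {
  ds <- generate_dataset(n_per_class, seed = seed, size = size,
                         noise_sd = noise_sd)
  feats <- extract_feature_table(ds$items,
                                 masks = if (use_masks) ds$masks else NULL)
  sp <- split_dataset(ds$labels, seed = seed)
  config$seed <- as.integer(seed)
  model <- train_mlp(feats[sp$train, , drop = FALSE], ds$labels[sp$train],
                     config = config,
                     val = list(x = feats[sp$validation, , drop = FALSE],
                                labels = ds$labels[sp$validation]))
  pred <- predict(model, feats[sp$test, , drop = FALSE])
  truth <- ds$labels[sp$test]
  cm <- confusion(truth, pred$class, classes = ds$classes)
  list(accuracy = mean(as.character(pred$class) == as.character(truth)),
       cm = cm, metrics = cm_metrics(cm),
       auc = roc_auc(pred$prob, truth),
       model = model, split = sp, labels = ds$labels, features = feats)
}
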