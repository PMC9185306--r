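#' Region of interest for feature extraction
#'
#' Crops an image to the bounding box of a binary mask and carries the mask
#' along, so that descriptors are computed from lesion pixels only. With
#' `mask = NULL` the whole frame is the ROI (whole-frame extraction is the
#' mode used when no segmentation is available).
#'
#' @param image [rgb_image], `H x W x 3` array, or grayscale matrix.
#' @param mask optional logical/0-1 matrix of the same `H x W`.
#' @return a `roi` list with elements `pixels` and `mask`.
#' @export
make_roi <- function(image, mask = NULL) {
  px <- if (is.array(image) && length(dim(image)) == 3L) {
    as_rgb_array(image)
  } else {
    as_gray_matrix(image)
  }
  d <- dim(px)
  if (is.null(mask)) {
    m <- matrix(TRUE, d[1], d[2])
  } else {
    m <- as.matrix(mask) > 0
    if (!all(dim(m) == d[1:2])) stop("mask shape must match the image",
                                     call. = FALSE)
    if (!any(m)) stop("mask has no foreground pixels", call. = FALSE)
    rr <- range(which(rowSums(m) > 0))
    cr <- range(which(colSums(m) > 0))
    px <- if (length(d) == 3L) px[rr[1]:rr[2], cr[1]:cr[2], , drop = FALSE] else
      px[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    m <- m[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  }
  if (sum(m) < 16) stop("ROI must contain at least 16 foreground pixels",
                        call. = FALSE)
  structure(list(pixels = px, mask = m), class = "roi")
}

roi_gray <- function(roi) {
  if (length(dim(roi$pixels)) == 3L) to_gray(rgb_image(roi$pixels)) else
    roi$pixels
}

as_roi <- function(x) {
  if (inherits(x, "roi")) x else make_roi(x)
}

#' Construct a typed feature vector
#'
#' A feature vector is a named numeric vector whose entries are tagged with
#' the descriptor block they came from (`lbp`, `glcm`, `fch` or `deep`), so
#' fused vectors keep their provenance.
#'
#' @param values numeric vector.
#' @param block single block tag, or a tag per value.
#' @return a `feature_vector`.
#' @export
feature_vector <- function(values, block) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  blocks <- if (length(block) == 1L) rep(block, length(values)) else block
  stopifnot(length(blocks) == length(values))
  if (is.null(names(values))) {
    names(values) <- paste0(blocks, "_", stats::ave(seq_along(blocks), blocks,
                                                    FUN = seq_along))
  }
  structure(values, blocks = blocks, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  tab <- table(attr(x, "blocks"))
  cat(sprintf("<feature_vector length %d: %s>\n", length(x),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Bilinear sample of gray at (ri + dr, ci + dc) for index vectors ri, ci.
# Offsets within 1e-9 of an integer are snapped so axial neighbours are
# read exactly.
sample_offset <- function(gray, ri, ci, dr, dc) {
  if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
  if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  out <- 0
  for (a in 0:1) {
    for (b in 0:1) {
      wgt <- (if (a == 0) 1 - fr else fr) * (if (b == 0) 1 - fc else fc)
      if (wgt == 0) next
      out <- out + wgt * gray[ri + r0 + a, ci + c0 + b]
    }
  }
  out
}

#' Local binary pattern histogram
#'
#' For every interior masked pixel, the `P` neighbours sampled circularly at
#' radius `R` (bilinear interpolation off-grid) are thresholded against the
#' centre with `s(x) = 1` if `x >= 0`, and combined into the code
#' `sum_p s(g_p - g_c) * 2^p`. Codes are histogrammed into `bins`
#' equal-width bins over `[0, 2^P - 1]` and normalized to sum 1. The
#' default 203 bins matches the published descriptor length; `bins = 256`
#' gives the exact one-bin-per-code histogram.
#'
#' @param roi a [make_roi] object, grayscale matrix, or RGB array (converted
#'   by channel averaging).
#' @param P number of circular neighbours (8).
#' @param R sampling radius in pixels.
#' @param bins histogram length.
#' @return a `feature_vector` of length `bins`, block `lbp`.
#' @export
lbp_features <- function(roi, P = 8L, R = 1, bins = 203L) {
  roi <- as_roi(roi)
  stopifnot(P == 8L, R >= 1, bins >= 2L)
  gray <- roi_gray(roi)
  margin <- ceiling(R)
  h <- nrow(gray); w <- ncol(gray)
  if (h < 2 * margin + 1 || w < 2 * margin + 1) {
    stop(sprintf("ROI (%d x %d) is smaller than the %d x %d LBP support",
                 h, w, 2 * margin + 1, 2 * margin + 1), call. = FALSE)
  }
  ri <- (margin + 1):(h - margin)
  ci <- (margin + 1):(w - margin)
  center <- gray[ri, ci]
  codes <- matrix(0, length(ri), length(ci))
  for (p in 0:(P - 1)) {
    a <- 2 * pi * p / P
    samp <- sample_offset(gray, ri, ci, dr = -R * sin(a), dc = R * cos(a))
    codes <- codes + 2^p * (samp >= center)
  }
  keep <- roi$mask[ri, ci]
  codes <- codes[keep]
  if (length(codes) == 0) stop("no interior masked pixels for LBP",
                               call. = FALSE)
  n_codes <- 2^P
  bin <- pmin(floor(codes * bins / n_codes) + 1L, bins)
  hist <- tabulate(bin, nbins = bins)
  feature_vector(hist / sum(hist), "lbp")
}

# equal-width quantization of masked pixels to 1..n_levels; shift-equivariant
quantize_levels <- function(gray, mask, n_levels) {
  vals <- gray[mask]
  rng <- range(vals)
  lev <- matrix(1L, nrow(gray), ncol(gray))
  if (diff(rng) > 0) {
    q <- floor((gray - rng[1]) / diff(rng) * n_levels) + 1L
    lev <- matrix(pmin(as.integer(q), as.integer(n_levels)),
                  nrow(gray), ncol(gray))
  }
  lev
}

# Accumulate one symmetric normalized co-occurrence table over masked pairs.
glcm_table <- function(lev, mask, dr, dc, n_levels) {
  h <- nrow(lev); w <- ncol(lev)
  r1 <- max(1, 1 - dr):min(h, h - dr)
  c1 <- max(1, 1 - dc):min(w, w - dc)
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + dr, c1 + dc, drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(ok)) return(NULL)
  idx <- (a[ok] - 1L) * n_levels + b[ok]
  counts <- matrix(tabulate(idx, nbins = n_levels^2), n_levels, n_levels,
                   byrow = TRUE)
  counts <- counts + t(counts)          # symmetric accumulation
  counts / sum(counts)
}

# entropy helper; natural logarithm, 0 log 0 := 0
entropy0 <- function(q) {
  q <- q[q > 0]
  if (length(q) == 0) return(0)
  -sum(q * log(q))
}

# The 13 classical co-occurrence statistics from one normalized table.
haralick13 <- function(p) {
  n <- nrow(p)
  i <- row(p); j <- col(p)
  lev <- seq_len(n)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  s <- i + j; dif <- abs(i - j)
  ks <- 2:(2 * n)
  p_sum <- vapply(ks, function(k) sum(p[s == k]), numeric(1))
  kd <- 0:(n - 1)
  p_diff <- vapply(kd, function(k) sum(p[dif == k]), numeric(1))
  ent <- entropy0(p)
  hx <- entropy0(px); hy <- entropy0(py)
  pxpy <- outer(px, py)
  nz <- pxpy > 0
  hxy1 <- -sum(p[nz] * log(pxpy[nz]))
  hxy2 <- -sum(pxpy[nz] * log(pxpy[nz]))
  sum_avg <- sum(ks * p_sum)
  diff_avg <- sum(kd * p_diff)
  c(energy = sum(p^2),
    contrast = sum(kd^2 * p_diff),
    correlation = if (sx == 0 || sy == 0) 0 else
      (sum(i * j * p) - mux * muy) / (sx * sy),
    variance = sum((i - mux)^2 * p),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    sum_average = sum_avg,
    sum_variance = sum((ks - sum_avg)^2 * p_sum),
    sum_entropy = entropy0(p_sum),
    entropy = ent,
    difference_variance = sum((kd - diff_avg)^2 * p_diff),
    difference_entropy = entropy0(p_diff),
    info_correlation_1 = if (max(hx, hy) == 0) 0 else (ent - hxy1) / max(hx, hy),
    info_correlation_2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - ent)))))
}

#' Grey-level co-occurrence (Haralick) texture features
#'
#' The ROI is quantized to `n_levels` equal-width grey levels, symmetric
#' normalized co-occurrence tables are accumulated over masked pixel pairs
#' for the four offsets (0 deg, d = 1), (45 deg, d = sqrt(2)),
#' (90 deg, d = 1) and (135 deg, d = sqrt(2)), and the 13 classical
#' statistics (energy, contrast, correlation, variance, inverse difference
#' moment, sum average, sum variance, sum entropy, entropy, difference
#' variance, difference entropy, and the two information measures of
#' correlation) are computed per offset and averaged. Correlation-type
#' statistics are defined as 0 when a marginal variance is 0.
#'
#' @param roi a [make_roi] object or grayscale matrix.
#' @param n_levels quantization depth.
#' @return a `feature_vector` of length 13, block `glcm`.
#' @export
glcm_features <- function(roi, n_levels = 32L) {
  roi <- as_roi(roi)
  gray <- roi_gray(roi)
  lev <- quantize_levels(gray, roi$mask, n_levels)
  # axial offsets at distance 1, diagonal offsets at distance sqrt(2)
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  feats <- NULL
  n_used <- 0L
  for (off in offsets) {
    tab <- glcm_table(lev, roi$mask, off[1], off[2], as.integer(n_levels))
    if (is.null(tab)) next
    f <- haralick13(tab)
    feats <- if (is.null(feats)) f else feats + f
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("ROI has no co-occurring masked pixel pairs",
                         call. = FALSE)
  if (length(unique(lev[roi$mask])) < 2L) {
    warning("degenerate ROI: a single grey level; correlation terms set to 0",
            call. = FALSE)
  }
  feature_vector(unname(feats / n_used), "glcm")
}

# 16 fixed colour bin centres: 4 (R) x 2 (G) x 2 (B) lattice of channel
# midpoints on the 0..255 scale; R index varies fastest.
fch_centers <- function() {
  g <- expand.grid(r = (c(0.5, 1.5, 2.5, 3.5) / 4) * 255,
                   g = (c(0.5, 1.5) / 2) * 255,
                   b = (c(0.5, 1.5) / 2) * 255)
  as.matrix(g)
}

#' Fuzzy colour histogram
#'
#' Pixels of an RGB ROI are spread over 16 fixed colour bin centres (a
#' 4x2x2 red/green/blue lattice of channel midpoints). In the default fuzzy
#' mode each pixel distributes graded membership over all centres,
#' proportional to `1 / (d^2 + tau)` with `d` the Euclidean RGB distance
#' (memberships normalized to 1 per pixel). In crisp mode each pixel is
#' assigned wholly to its nearest centre. Either way the histogram is
#' normalized to sum 1.
#'
#' @param roi a [make_roi] object or `H x W x 3` array; grayscale input is
#'   an error.
#' @param bins number of colour bins (16 for the standard lattice).
#' @param mode `"fuzzy"` (default) or `"crisp"`.
#' @param tau softness constant in the fuzzy membership (also guards the
#'   division).
#' @return a `feature_vector` of length `bins`, block `fch`.
#' @export
fch_features <- function(roi, bins = 16L, mode = c("fuzzy", "crisp"),
                         tau = 1) {
  roi <- as_roi(roi)
  mode <- match.arg(mode)
  if (length(dim(roi$pixels)) != 3L) {
    stop("FCH needs an RGB ROI; got a single-channel raster", call. = FALSE)
  }
  if (bins != 16L) {
    stop("the colour lattice defines 16 bins; `bins` must be 16",
         call. = FALSE)
  }
  centers <- fch_centers()
  m <- roi$mask
  pix <- cbind(roi$pixels[, , 1][m], roi$pixels[, , 2][m], roi$pixels[, , 3][m])
  d2 <- outer(rowSums(pix^2), rep(1, nrow(centers))) -
    2 * pix %*% t(centers) +
    outer(rep(1, nrow(pix)), rowSums(centers^2))
  d2[d2 < 0] <- 0  # numerical guard
  if (mode == "crisp") {
    bin <- max.col(-d2, ties.method = "first")
    hist <- tabulate(bin, nbins = nrow(centers))
    feature_vector(hist / sum(hist), "fch")
  } else {
    mem <- 1 / (d2 + tau)
    mem <- mem / rowSums(mem)
    feature_vector(colSums(mem) / nrow(pix), "fch")
  }
}

#' Fuse descriptor blocks into one feature vector
#'
#' Plain ordered concatenation; block tags are preserved, so the fused
#' vector still knows which entries are LBP, co-occurrence, colour or deep
#' features. Fusing the standard LBP (203) + GLCM (13) + FCH (16) blocks
#' yields the 232-dimensional handcrafted descriptor.
#'
#' @param ... `feature_vector` objects, or a single list of them.
#' @return the concatenated `feature_vector`.
#' @export
fuse_features <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && is.list(blocks[[1]]) &&
      !inherits(blocks[[1]], "feature_vector")) {
    blocks <- blocks[[1]]
  }
  if (length(blocks) == 0L) stop("need at least one feature block",
                                 call. = FALSE)
  for (b in blocks) {
    if (!inherits(b, "feature_vector")) {
      stop("all blocks must be feature_vector objects", call. = FALSE)
    }
  }
  vals <- unlist(lapply(blocks, as.numeric), use.names = FALSE)
  tags <- unlist(lapply(blocks, attr, "blocks"), use.names = FALSE)
  nms <- unlist(lapply(blocks, names), use.names = FALSE)
  out <- feature_vector(stats::setNames(vals, nms), tags)
  out
}

#' Seeded fallback embedding extractor
#'
#' A deterministic stand-in for a learned embedding network: the image is
#' downsampled to a `grid x grid` block-mean thumbnail per channel and
#' passed through a fixed random linear projection drawn once from the
#' seed. It exercises the plumbing and dimensionality of deep-feature
#' fusion (the conventional embedding width is 4096); it carries no learned
#' semantics.
#'
#' @param width output width.
#' @param seed RNG seed fixing the projection.
#' @param grid thumbnail side length.
#' @return a `feature_extractor` with fields `width` and `fn`.
#' @export
fallback_extractor <- function(width = 4096L, seed = 0L, grid = 16L) {
  d_in <- 3L * grid^2 + 1L
  W <- withr::with_seed(seed,
    matrix(stats::rnorm(width * d_in), as.integer(width), d_in) / sqrt(d_in))
  fn <- function(image) {
    px <- as_rgb_array(image)
    v <- unlist(lapply(1:3, function(ch) block_mean(px[, , ch], grid)),
                use.names = FALSE)
    as.numeric(W %*% c(v / 255, 1))
  }
  structure(list(width = as.integer(width), seed = as.integer(seed),
                 grid = as.integer(grid), fn = fn),
            class = "feature_extractor")
}

# block-mean downsample of a matrix to grid x grid
block_mean <- function(x, grid) {
  rb <- floor((seq_len(nrow(x)) - 1L) * grid / nrow(x)) + 1L
  cb <- floor((seq_len(ncol(x)) - 1L) * grid / ncol(x)) + 1L
  sums <- rowsum(t(rowsum(x, rb)), cb)         # grid x grid totals
  cnt <- outer(tabulate(cb, grid), tabulate(rb, grid))
  as.numeric(t(sums / cnt))
}

#' Extract a deep-embedding feature block
#'
#' Runs a pluggable extractor (any object with a declared `width` and a
#' `fn(image)` returning that many numbers) and tags the result as the
#' `deep` block. The bundled [fallback_extractor] is the default.
#'
#' @param image an [rgb_image] or `H x W x 3` array.
#' @param extractor a `feature_extractor`.
#' @return a `feature_vector` of length `extractor$width`, block `deep`.
#' @export
deep_extract <- function(image, extractor = fallback_extractor()) {
  stopifnot(inherits(extractor, "feature_extractor"))
  v <- extractor$fn(image)
  if (length(v) != extractor$width) {
    stop(sprintf("extractor contract violation: declared width %d, returned %d",
                 extractor$width, length(v)), call. = FALSE)
  }
  feature_vector(v, "deep")
}

#' Fuse a deep block with the handcrafted descriptor
#'
#' Concatenation deep-then-handcrafted; with a 4096-wide embedding and the
#' 232-dimensional handcrafted block this yields the 4328-dimensional
#' hybrid vector.
#'
#' @param deep `feature_vector` from [deep_extract].
#' @param handcrafted fused `feature_vector` containing `lbp`, `glcm` and
#'   `fch` blocks.
#' @return the hybrid `feature_vector`.
#' @export
fuse_deep <- function(deep, handcrafted) {
  stopifnot(inherits(deep, "feature_vector"),
            inherits(handcrafted, "feature_vector"))
  have <- unique(attr(handcrafted, "blocks"))
  need <- c("lbp", "glcm", "fch")
  if (!all(need %in% have)) {
    stop(sprintf("handcrafted block is missing: %s",
                 paste(setdiff(need, have), collapse = ", ")), call. = FALSE)
  }
  fuse_features(deep, handcrafted)
}
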