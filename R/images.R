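#' Construct and validate an 8-bit RGB image
#'
#' Endoscopy frames are handled as plain `H x W x 3` numeric arrays with
#' values on the 0--255 scale. `rgb_image()` validates an array and tags it
#' with the `rgb_image` class; every downstream operation accepts either the
#' tagged object or a raw array of the same layout.
#'
#' @param pixels numeric array, `H x W x 3`, values in `[0, 255]`.
#' @return the validated array with class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array (exactly 3 colour channels)",
         call. = FALSE)
  }
  d <- dim(pixels)
  if (d[1] < 16L || d[2] < 16L) {
    stop("image must be at least 16 x 16 pixels", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("pixel values must be finite", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  structure(pixels, class = c("rgb_image", class(unclass(pixels))))
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, range [%.1f, %.1f]>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

# Accept rgb_image or bare array; return validated bare array.
as_rgb_array <- function(image) {
  if (inherits(image, "rgb_image")) return(unclass(image))
  unclass(rgb_image(image))
}

# Grayscale planes are bare numeric matrices; validate shape/finiteness.
as_gray_matrix <- function(gray) {
  if (is.array(gray) && length(dim(gray)) == 3L) {
    stop("expected a single-plane grayscale matrix, got a 3-channel array",
         call. = FALSE)
  }
  gray <- as.matrix(gray)
  if (!is.numeric(gray)) stop("grayscale image must be numeric", call. = FALSE)
  if (anyNA(gray) || any(!is.finite(gray))) {
    stop("grayscale values must be finite", call. = FALSE)
  }
  gray
}

#' Read an 8-bit image from a PNG file
#'
#' @param path file path to a PNG image.
#' @return an [rgb_image] (grayscale files are replicated across channels).
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  rgb_image(px[, , 1:3, drop = FALSE] * 255)
}

#' Write an image or mask to a PNG file
#'
#' Real-valued planes are clipped to `[0, 255]` and rounded only here, at
#' export time; in-memory arithmetic stays in double precision.
#'
#' @param pixels matrix (gray / mask) or `H x W x 3` array.
#' @param path output file path.
#' @export
write_image <- function(pixels, path) {
  px <- unclass(pixels)
  px <- pmin(pmax(px, 0), 255)
  png::writePNG(round(px) / 255, path)
  invisible(path)
}

#' Write a real-valued plane losslessly as tab-separated text
#'
#' Full-precision sidecar for enhanced images and level-set fields, so that
#' downstream stages can consume exact values rather than 8-bit quantized
#' PNG output.
#'
#' @param x numeric matrix.
#' @param path output path.
#' @export
write_matrix_txt <- function(x, path) {
  utils::write.table(format(as.matrix(x), digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}

# ---- low-level raster helpers -------------------------------------------

# Replicate-pad a matrix by m rows/cols on every side.
pad_replicate <- function(x, m) {
  h <- nrow(x); w <- ncol(x)
  ri <- c(rep(1L, m), seq_len(h), rep(h, m))
  ci <- c(rep(1L, m), seq_len(w), rep(w, m))
  x[ri, ci, drop = FALSE]
}

# 2-D correlation with replicate padding; kernel must be odd-sized square.
conv2_replicate <- function(x, kern) {
  k <- nrow(kern)
  stopifnot(k == ncol(kern), k %% 2L == 1L)
  m <- (k - 1L) %/% 2L
  p <- pad_replicate(x, m)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (dr in seq_len(k)) {
    for (dc in seq_len(k)) {
      wgt <- kern[dr, dc]
      if (wgt == 0) next
      out <- out + wgt * p[(dr - 1L) + seq_len(h), (dc - 1L) + seq_len(w)]
    }
  }
  out
}

# Separable Gaussian smoothing (replicate borders), used to regularize phi.
gaussian_smooth <- function(x, sigma = 1, half_width = 2L) {
  t <- seq(-half_width, half_width)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  conv2_replicate(x, outer(g, g))
}

# Grow a logical seed inside a logical region by 4-connected dilation until
# a fixed point; the workhorse behind hole filling and component picking.
propagate_region <- function(seed, region) {
  cur <- seed & region
  h <- nrow(cur); w <- ncol(cur)
  repeat {
    grown <- cur
    grown[-1, ] <- grown[-1, ] | cur[-h, ]
    grown[-h, ] <- grown[-h, ] | cur[-1, ]
    grown[, -1] <- grown[, -1] | cur[, -w]
    grown[, -w] <- grown[, -w] | cur[, -1]
    grown <- grown & region
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

# round-half-up at integer granularity (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)
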