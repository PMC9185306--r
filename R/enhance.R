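#' Convert an RGB frame to grayscale by channel averaging
#'
#' Each output pixel is the unweighted mean of its red, green and blue
#' values. Channel averaging (rather than luminance weighting) keeps the
#' grayscale plane faithful to the colour balance of endoscopic mucosa,
#' where all three channels carry diagnostic signal.
#'
#' @param image an [rgb_image] or `H x W x 3` array on the 0--255 scale.
#' @return numeric `H x W` matrix.
#' @export
to_gray <- function(image) {
  px <- as_rgb_array(image)
  (px[, , 1] + px[, , 2] + px[, , 3]) / 3
}

#' Neighbourhood averaging filter (centre pixel excluded)
#'
#' Replaces every pixel by the mean of the other `window^2 - 1` pixels in
#' its square window; with the default 5 x 5 window each pixel becomes the
#' average of its 24 adjacent pixels. Borders are handled by edge
#' replication. Set `include_center = TRUE` for the conventional inclusive
#' `window^2`-cell box mean.
#'
#' @param gray numeric matrix.
#' @param window odd window side length, `>= 3`.
#' @param include_center logical; include the centre pixel in the mean?
#' @return smoothed matrix, same shape.
#' @export
average_filter <- function(gray, window = 5L, include_center = FALSE) {
  gray <- as_gray_matrix(gray)
  if (length(window) != 1L || window < 3L || window %% 2L != 1L) {
    stop("`window` must be a single odd integer >= 3", call. = FALSE)
  }
  kern <- matrix(1, window, window)
  mid <- (window + 1L) %/% 2L
  if (!include_center) kern[mid, mid] <- 0
  conv2_replicate(gray, kern / sum(kern))
}

#' Discrete Laplacian filter
#'
#' Second-derivative edge response \eqn{\nabla^2 f}; raises lesion
#' boundaries above the smooth mucosal background. The 4-connected stencil
#' `[[0,1,0],[1,-4,1],[0,1,0]]` is the default; an 8-connected stencil is
#' available via `kernel = "8"`. Borders are replicate-padded, so the
#' response to a constant image is exactly zero everywhere.
#'
#' @param gray numeric matrix.
#' @param kernel `"4"` (default) or `"8"` connectivity.
#' @return Laplacian response matrix, same shape.
#' @export
laplacian_filter <- function(gray, kernel = c("4", "8")) {
  gray <- as_gray_matrix(gray)
  kernel <- match.arg(as.character(kernel[1]), c("4", "8"))
  kern <- if (kernel == "4") {
    matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  } else {
    matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3)
  }
  conv2_replicate(gray, kern)
}

#' Enhance an endoscopy frame
#'
#' The enhancement chain: grayscale conversion by channel averaging, a
#' centre-excluded averaging filter to suppress specular/fluid artifacts,
#' and a Laplacian filter to localize lesion edges. The enhanced plane is
#' the smoothed image minus the Laplacian response,
#' `average_filter(gray) - laplacian_filter(gray)`, which both denoises and
#' sharpens boundaries. Values are kept real-valued; clip/quantize only on
#' export ([write_image]).
#'
#' @param image an [rgb_image] or `H x W x 3` array.
#' @param window averaging window side length (odd, default 5).
#' @param kernel Laplacian connectivity, `"4"` or `"8"`.
#' @param include_center include the centre pixel in the box mean?
#' @return numeric matrix with attribute `"provenance"` recording the
#'   parameters used.
#' @export
enhance <- function(image, window = 5L, kernel = "4", include_center = FALSE) {
  gray <- to_gray(image)
  out <- average_filter(gray, window = window, include_center = include_center) -
    laplacian_filter(gray, kernel = kernel)
  attr(out, "provenance") <- list(window = as.integer(window),
                                  kernel = kernel,
                                  include_center = include_center)
  out
}
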