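#' The five phantom classes
#'
#' Class list of the emulated lower-GI endoscopy setting: two normal
#' anatomical landmarks and three lesion-bearing findings.
#'
#' @export
phantom_classes <- function() {
  c("dyed-lifted-polyps", "normal-cecum", "normal-pylorus", "polyps",
    "ulcerative-colitis")
}

# class-conditional generative parameters; the base colours live in
# disjoint intervals so mean colour alone already separates classes
phantom_palette <- list(
  "dyed-lifted-polyps" = list(base = c(200, 140, 130), tex_freq = 0.06,
                              tex_amp = 8, lesion = c(5, 55, 95)),
  "normal-cecum"       = list(base = c(205, 152, 142), tex_freq = 0.05,
                              tex_amp = 8, lesion = NULL),
  "normal-pylorus"     = list(base = c(215, 178, 108), tex_freq = 0.16,
                              tex_amp = 12, lesion = NULL),
  "polyps"             = list(base = c(188, 128, 120), tex_freq = 0.09,
                              tex_amp = 10, lesion = c(248, 208, 186)),
  "ulcerative-colitis" = list(base = c(216, 166, 150), tex_freq = 0.11,
                              tex_amp = 9, lesion = c(160, 25, 20)))

#' Specify an endoscopy-like phantom
#'
#' Draws the per-image generative parameters (colour jitter, vignette
#' strength, texture phase, lesion geometry) deterministically from the
#' seed and freezes them in a spec, so the analytic lesion area is known
#' before the image is rendered. Lesion colours sit at least 60 grey
#' levels away from the class base colour pre-noise, and lesion geometry is
#' constrained to keep masks off the image border.
#'
#' @param class one of [phantom_classes()].
#' @param size square image side, `>= 64`.
#' @param noise_sd additive Gaussian noise sigma on the 0--255 scale.
#' @param seed RNG seed; the whole phantom is a pure function of
#'   `(class, size, noise_sd, seed)`.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(class, size = 128L, noise_sd = 5, seed = 1L) {
  class <- match.arg(class, phantom_classes())
  size <- as.integer(size)
  if (size < 64L) stop("phantom size must be at least 64 pixels",
                       call. = FALSE)
  pal <- phantom_palette[[class]]
  par <- withr::with_seed(seed, {
    p <- list(
      base = pmin(pmax(pal$base + stats::runif(3, -8, 8), 0), 255),
      vignette = stats::runif(1, 0.15, 0.3),
      tex_phase = stats::runif(2, 0, 2 * pi),
      tex_angle = stats::runif(1, 0, pi))
    if (!is.null(pal$lesion)) {
      margin <- 6
      if (class == "ulcerative-colitis") {
        p$lesion_r <- stats::runif(1, 0.18, 0.24) * size
        p$wave_amp <- stats::runif(1, 0.08, 0.15)
        p$wave_phase <- stats::runif(1, 0, 2 * pi)
        max_r <- p$lesion_r * (1 + p$wave_amp)
      } else {
        p$axes <- stats::runif(2, 0.10, 0.16) * size
        p$theta <- stats::runif(1, 0, pi)
        max_r <- max(p$axes)
        if (class == "dyed-lifted-polyps") {
          # a second overlapping blob makes the lifted shape
          p$blob2_shift <- stats::runif(1, 0.3, 0.5) * min(p$axes)
          p$blob2_scale <- stats::runif(1, 0.5, 0.7)
          max_r <- max_r + p$blob2_shift
        }
        if (class == "polyps") {
          p$spot_frac <- stats::runif(1, 0.12, 0.2)   # specular spot size
        }
      }
      jit <- size / 2 - max_r - margin
      jit <- min(jit, 0.08 * size)
      p$center <- size / 2 + stats::runif(2, -jit, jit)
    }
    p
  })
  structure(c(list(class = class, size = size, noise_sd = noise_sd,
                   seed = as.integer(seed)), par),
            class = "phantom_spec")
}

# pixel-centre coordinate grids
coord_grids <- function(size) {
  list(r = matrix(seq_len(size), size, size),
       c = matrix(seq_len(size), size, size, byrow = TRUE))
}

ellipse_mask <- function(size, center, axes, theta) {
  g <- coord_grids(size)
  dr <- g$r - center[1]; dc <- g$c - center[2]
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

#' Render a phantom image (and its lesion mask) from a spec
#'
#' Builds the mucosa-coloured field with a radial vignette and a
#' low-frequency sinusoidal texture, stamps the class's lesion (an ellipse
#' blob with a specular spot for polyps; a double blob under a blue-green
#' dye patch for dyed-lifted polyps; a wavy-edged diffusely reddened region
#' with granular noise for ulcerative colitis; none for the two normal
#' classes), then adds seeded Gaussian noise and clamps to `[0, 255]`.
#'
#' @param spec a [phantom_spec].
#' @return `list(image = rgb_image, mask = logical matrix or NULL,
#'   spec = spec)`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  size <- spec$size
  g <- coord_grids(size)
  pal <- phantom_palette[[spec$class]]

  # shading shared by the three channels
  rad2 <- ((g$r - size / 2)^2 + (g$c - size / 2)^2) / (size / 2)^2
  shade <- 1 - spec$vignette * rad2
  tex <- pal$tex_amp *
    sin(2 * pi * pal$tex_freq *
          (g$r * cos(spec$tex_angle) + g$c * sin(spec$tex_angle)) +
          spec$tex_phase[1]) *
    cos(2 * pi * pal$tex_freq * 0.63 *
          (g$c * cos(spec$tex_angle) - g$r * sin(spec$tex_angle)) +
          spec$tex_phase[2])

  img <- array(0, c(size, size, 3))
  for (ch in 1:3) img[, , ch] <- spec$base[ch] * shade + tex

  mask <- NULL
  if (!is.null(pal$lesion)) {
    if (spec$class == "ulcerative-colitis") {
      dr <- g$r - spec$center[1]; dc <- g$c - spec$center[2]
      ang <- atan2(dc, dr)
      mask <- sqrt(dr^2 + dc^2) <=
        spec$lesion_r * (1 + spec$wave_amp * sin(5 * ang + spec$wave_phase))
    } else {
      mask <- ellipse_mask(size, spec$center, spec$axes, spec$theta)
      if (spec$class == "dyed-lifted-polyps") {
        c2 <- spec$center + c(spec$blob2_shift, spec$blob2_shift) / sqrt(2)
        mask <- mask | ellipse_mask(size, c2, spec$axes * spec$blob2_scale,
                                    spec$theta)
      }
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- pal$lesion[ch]
      img[, , ch] <- plane
    }
    if (spec$class == "dyed-lifted-polyps") {
      # blue-green dye tint over a halo around the lifted blob
      halo_r <- max(spec$axes) + spec$blob2_shift + 4
      halo <- sqrt((g$r - spec$center[1])^2 + (g$c - spec$center[2])^2) <=
        halo_r
      tintable <- halo & !mask
      tint <- c(80, 160, 150)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[tintable] <- 0.65 * plane[tintable] + 0.35 * tint[ch]
        img[, , ch] <- plane
      }
    }
    if (spec$class == "polyps") {
      spot <- sqrt((g$r - spec$center[1])^2 + (g$c - spec$center[2])^2) <=
        spec$spot_frac * min(spec$axes)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[spot] <- 252
        img[, , ch] <- plane
      }
    }
  }

  noise_seed <- spec$seed + 1000003L
  img <- img + withr::with_seed(noise_seed, {
    n <- array(stats::rnorm(size * size * 3, 0, spec$noise_sd),
               c(size, size, 3))
    if (spec$class == "ulcerative-colitis") {
      # granular high-frequency speckle over the inflamed region
      gran <- matrix(stats::runif(size * size, -12, 12), size, size)
      gran[!mask] <- 0
      n <- n + outer(gran, c(1, 1, 1))
    }
    n
  })
  img <- pmin(pmax(img, 0), 255)
  list(image = rgb_image(img), mask = mask, spec = spec)
}

# bounded deterministic per-image seed from (master, class index, item)
derive_seed <- function(seed, class_idx, item) {
  (((seed %% 1000003L) * 2053L + class_idx * 100003L + item * 7919L) %%
     2147483629L) + 1L
}

#' Generate a balanced 5-class labelled phantom dataset
#'
#' `n_per_class` phantoms per class under derived per-image seeds, with
#' ground-truth masks for the lesion-bearing classes.
#'
#' @param n_per_class images per class, `>= 10`.
#' @param seed master seed.
#' @param size image side length.
#' @param noise_sd Gaussian noise sigma.
#' @return `list(items, labels, masks, classes, role = "all", specs)`.
#' @export
generate_dataset <- function(n_per_class, seed = 1L, size = 128L,
                             noise_sd = 5) {
  if (n_per_class < 10) stop("need at least 10 images per class",
                             call. = FALSE)
  classes <- phantom_classes()
  n <- n_per_class * length(classes)
  items <- vector("list", n)
  masks <- vector("list", n)
  specs <- vector("list", n)
  labels <- character(n)
  i <- 0L
  for (k in seq_along(classes)) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      sp <- phantom_spec(classes[k], size = size, noise_sd = noise_sd,
                         seed = derive_seed(as.integer(seed), k, j))
      ph <- generate_phantom(sp)
      items[[i]] <- ph$image
      masks[i] <- list(ph$mask)
      specs[[i]] <- sp
      labels[i] <- classes[k]
    }
  }
  list(items = items, labels = factor(labels, levels = classes),
       masks = masks, classes = classes, role = "all", specs = specs)
}

#' Disc phantom with exact ground truth
#'
#' Centred disc of intensity `fg` on a `bg` background plus seeded Gaussian
#' noise; the exact mask is returned alongside. The standard fixture for
#' segmentation properties.
#'
#' @param size image side length.
#' @param radius disc radius, `< size / 2`.
#' @param fg,bg foreground/background intensities.
#' @param noise_sd Gaussian noise sigma; a contrast below `4 * noise_sd`
#'   triggers a warning.
#' @param seed RNG seed for the noise field.
#' @return `list(gray = matrix, mask = logical matrix, degenerate =
#'   logical)`.
#' @export
generate_disc <- function(size = 128L, radius = 30, fg = 200, bg = 50,
                          noise_sd = 0, seed = 1L) {
  stopifnot(radius < size / 2)
  degenerate <- fg == bg
  if (!degenerate && noise_sd > 0 && abs(fg - bg) < 4 * noise_sd) {
    warning("contrast below 4 sigma; segmentation properties not guaranteed",
            call. = FALSE)
  }
  g <- coord_grids(size)
  mask <- sqrt((g$r - (size + 1) / 2)^2 + (g$c - (size + 1) / 2)^2) <= radius
  gray <- matrix(bg, size, size)
  gray[mask] <- fg
  if (noise_sd > 0) {
    gray <- gray + withr::with_seed(seed,
      matrix(stats::rnorm(size * size, 0, noise_sd), size, size))
  }
  list(gray = gray, mask = mask, degenerate = degenerate)
}
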