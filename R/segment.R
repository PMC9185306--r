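#' Parameters for region-based level-set segmentation
#'
#' @param lambda length-term weight, `> 0` (scales the `|grad phi|` speed).
#' @param nu signed area-term weight; positive inflates, negative deflates.
#' @param eps Heaviside smoothing width in pixels (width of the inside /
#'   outside transition band).
#' @param dt evolution time step.
#' @param sv stop value in percent: evolution stops when the mask area
#'   changes by less than `sv`% of the previous area between iterations.
#' @param max_iter iteration cap.
#' @param smooth_sigma Gaussian sigma used to re-regularize `phi` each step.
#' @return a `contour_params` list.
#' @export
contour_params <- function(lambda = 1, nu = 0, eps = 1.5, dt = 1,
                           sv = 0.1, max_iter = 500L, smooth_sigma = 1) {
  stopifnot(lambda > 0, eps > 0, dt > 0, sv > 0, max_iter >= 1)
  structure(list(lambda = lambda, nu = nu, eps = eps, dt = dt, sv = sv,
                 max_iter = as.integer(max_iter), smooth_sigma = smooth_sigma),
            class = "contour_params")
}

# smoothed Heaviside H_eps(t) = 1/2 (1 + 2/pi * atan(t/eps))
heaviside_eps <- function(t, eps) 0.5 * (1 + (2 / pi) * atan(t / eps))

#' Initialize the level-set state from a seed point
#'
#' `phi` is set to `radius - distance_to_seed`, i.e. positive inside a disc
#' of the given radius centred on the seed, negative outside; the binary
#' mask is the indicator `phi > 0` and is kept consistent with `phi` by
#' every subsequent operation.
#'
#' @param shape integer `c(H, W)`.
#' @param seed integer `c(row, col)` of the initial point.
#' @param radius initial disc radius in pixels, `>= 2`.
#' @return a `level_set_state` list: `phi`, `mask`, `c1`, `c2`, `iteration`,
#'   `area_history`, `converged`, `seed`.
#' @export
initialize_level_set <- function(shape, seed, radius = 5) {
  stopifnot(length(shape) == 2L, length(seed) == 2L, radius >= 2)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (seed[1] < 1 || seed[1] > h || seed[2] < 1 || seed[2] > w) {
    stop("seed point lies outside the image bounds", call. = FALSE)
  }
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  # tiny offset makes the disc boundary-inclusive: lattice points exactly at
  # the nominal radius belong to the seed region
  phi <- radius - sqrt((rr - seed[1])^2 + (cc - seed[2])^2) + 1e-9
  mask <- phi > 0
  structure(list(phi = phi, mask = mask, c1 = NA_real_, c2 = NA_real_,
                 iteration = 0L, area_history = sum(mask),
                 converged = FALSE, seed = as.integer(seed)),
            class = "level_set_state")
}

#' Inside / outside region means of the current contour
#'
#' Smoothed-Heaviside weighted means of the image over the inside
#' (`H_eps(phi)`) and outside (`1 - H_eps(phi)`) regions, optionally
#' restricted to a domain window `Mk` (all ones by default):
#' `c1 = sum(I * H * Mk) / sum(H * Mk)` and
#' `c2 = sum(I * (1 - H) * Mk) / sum((1 - H) * Mk)`.
#'
#' @param gray numeric image matrix.
#' @param state a `level_set_state`.
#' @param eps Heaviside smoothing width.
#' @param window optional 0/1 domain window (the characteristic function of
#'   the sub-region under consideration).
#' @return numeric `c(c1, c2)`.
#' @export
region_means <- function(gray, state, eps = 1.5, window = NULL) {
  gray <- as_gray_matrix(gray)
  H <- heaviside_eps(state$phi, eps)
  mk <- if (is.null(window)) 1 else as.numeric(window)
  w_in <- sum(H * mk)
  w_out <- sum((1 - H) * mk)
  if (w_in <= 0) stop("degenerate region: inside weight is empty", call. = FALSE)
  if (w_out <= 0) stop("degenerate region: outside weight is empty", call. = FALSE)
  c(sum(gray * H * mk) / w_in, sum(gray * (1 - H) * mk) / w_out)
}

# |grad phi| by central differences, replicate borders
grad_norm <- function(phi) {
  h <- nrow(phi); w <- ncol(phi)
  up <- phi[c(1, seq_len(h - 1)), ]
  dn <- phi[c(seq_len(h - 1) + 1, h), ]
  lf <- phi[, c(1, seq_len(w - 1))]
  rt <- phi[, c(seq_len(w - 1) + 1, w)]
  sqrt(((dn - up) / 2)^2 + ((rt - lf) / 2)^2)
}

#' One evolution step of the region-based contour
#'
#' Updates `phi <- phi + dt * spf * (lambda * |grad phi| + nu)` where the
#' signed pressure force is
#' `spf = (I - (c1 + c2)/2) / max|I - (c1 + c2)/2|`, then re-regularizes
#' `phi` with a small Gaussian and recomputes the mask. On an all-constant
#' image the drive is undefined; the state is returned unchanged with
#' `converged = TRUE`.
#'
#' @param gray numeric image matrix.
#' @param state a `level_set_state`.
#' @param params a [contour_params] list.
#' @return the updated `level_set_state`.
#' @export
evolve_step <- function(gray, state, params = contour_params()) {
  gray <- as_gray_matrix(gray)
  cm <- region_means(gray, state, eps = params$eps)
  drive <- gray - (cm[1] + cm[2]) / 2
  dmax <- max(abs(drive))
  if (dmax == 0) {
    state$converged <- TRUE
    state$c1 <- cm[1]; state$c2 <- cm[2]
    return(state)
  }
  spf <- drive / dmax
  phi <- state$phi + params$dt * spf * (params$lambda * grad_norm(state$phi) +
                                          params$nu)
  phi <- gaussian_smooth(phi, sigma = params$smooth_sigma)
  state$phi <- phi
  state$mask <- phi > 0
  state$c1 <- cm[1]; state$c2 <- cm[2]
  state$iteration <- state$iteration + 1L
  state$area_history <- c(state$area_history, sum(state$mask))
  state
}

#' Stopping rule on the contour's mask area
#'
#' The evolution is declared stationary when the mask area changes by less
#' than `sv` percent of the previous area between successive iterations:
#' `|area_new - area_old| < (sv/100) * area_old`. An empty previous contour
#' cannot evolve further and always stops.
#'
#' @param area_old,area_new pixel counts of the previous and current masks.
#' @param sv stop value in percent, `> 0`.
#' @return logical.
#' @export
stop_criterion <- function(area_old, area_new, sv) {
  stopifnot(area_old >= 0, area_new >= 0, sv > 0)
  if (area_old == 0) return(TRUE)
  abs(area_new - area_old) < (sv / 100) * area_old
}

#' Segment a lesion with a seeded region-based level set
#'
#' Evolves the contour from a seeded disc until the area-based
#' [stop_criterion] fires or `max_iter` is reached, then returns the
#' 4-connected component of the final mask that contains the seed, which
#' isolates the seeded lesion from any other regions the evolution may have
#' captured.
#'
#' @param gray numeric image matrix (typically an [enhance]d frame or the
#'   grayscale plane).
#' @param seed integer `c(row, col)` inside the lesion.
#' @param radius initial disc radius.
#' @param params a [contour_params] list.
#' @return logical mask matrix with attributes `"iterations"`,
#'   `"stopped_by"` (`"area"`, `"converged"` or `"max_iter"`).
#' @export
segment_lesion <- function(gray, seed, radius = 5, params = contour_params()) {
  gray <- as_gray_matrix(gray)
  state <- initialize_level_set(dim(gray), seed, radius)
  stopped_by <- "max_iter"
  for (i in seq_len(params$max_iter)) {
    area_old <- sum(state$mask)
    state <- evolve_step(gray, state, params)
    if (state$converged) {
      stopped_by <- "converged"
      break
    }
    if (stop_criterion(area_old, sum(state$mask), params$sv)) {
      stopped_by <- "area"
      break
    }
  }
  mask <- state$mask
  # keep only the component the seed belongs to
  if (mask[state$seed[1], state$seed[2]]) {
    seed_m <- matrix(FALSE, nrow(mask), ncol(mask))
    seed_m[state$seed[1], state$seed[2]] <- TRUE
    mask <- propagate_region(seed_m, mask)
  }
  structure(mask, iterations = state$iteration, stopped_by = stopped_by)
}

#' Fill interior holes of a binary mask
#'
#' Every background region not 4-connected to the image border is switched
#' to foreground. Idempotent; a concavity open to the border is left alone.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  m <- as.matrix(mask) > 0
  bg <- !m
  border <- matrix(FALSE, nrow(m), ncol(m))
  border[1, ] <- TRUE; border[nrow(m), ] <- TRUE
  border[, 1] <- TRUE; border[, ncol(m)] <- TRUE
  reachable <- propagate_region(border & bg, bg)
  m | (bg & !reachable)
}
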