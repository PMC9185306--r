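# Independent brute-force oracles: every routine here recomputes a quantity
# by direct enumeration (nested loops, pair counting), deliberately sharing
# no code with the package implementations they check.

# clamp an index into 1..n (replicate-border convention)
clampi <- function(i, n) pmin(pmax(i, 1L), n)

# windowed mean with replicate padding, centre optionally excluded
oracle_average_filter <- function(x, window = 5L, include_center = FALSE) {
  h <- nrow(x); w <- ncol(x)
  m <- (window - 1L) %/% 2L
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      acc <- 0; cnt <- 0
      for (dr in -m:m) {
        for (dc in -m:m) {
          if (!include_center && dr == 0 && dc == 0) next
          acc <- acc + x[clampi(r + dr, h), clampi(c + dc, w)]
          cnt <- cnt + 1
        }
      }
      out[r, c] <- acc / cnt
    }
  }
  out
}

# explicit stencil sum with replicate padding
oracle_laplacian <- function(x, eight = FALSE) {
  kern <- if (eight) {
    matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3)
  } else {
    matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  }
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      acc <- 0
      for (dr in -1:1) {
        for (dc in -1:1) {
          acc <- acc + kern[dr + 2, dc + 2] *
            x[clampi(r + dr, h), clampi(c + dc, w)]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# scalar bilinear read at fractional position (pr, pc)
oracle_bilinear <- function(x, pr, pc) {
  r0 <- floor(pr); c0 <- floor(pc)
  fr <- pr - r0; fc <- pc - c0
  v <- 0
  for (a in 0:1) {
    for (b in 0:1) {
      wt <- (if (a == 0) 1 - fr else fr) * (if (b == 0) 1 - fc else fc)
      if (wt > 0) v <- v + wt * x[r0 + a, c0 + b]
    }
  }
  v
}

# per-pixel circular LBP code, bit by bit
oracle_lbp_code <- function(x, r, c, P = 8, R = 1) {
  gc <- x[r, c]
  code <- 0
  for (p in 0:(P - 1)) {
    a <- 2 * pi * p / P
    dr <- -R * sin(a); dc <- R * cos(a)
    if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
    if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
    gp <- oracle_bilinear(x, r + dr, c + dc)
    if (gp - gc >= 0) code <- code + 2^p
  }
  code
}

# full LBP histogram over interior pixels via the per-pixel oracle
oracle_lbp_hist <- function(x, bins = 203, P = 8, R = 1) {
  h <- nrow(x); w <- ncol(x)
  codes <- c()
  for (r in 2:(h - 1)) {
    for (c in 2:(w - 1)) {
      codes <- c(codes, oracle_lbp_code(x, r, c, P, R))
    }
  }
  hist <- rep(0, bins)
  for (cd in codes) {
    b <- min(floor(cd * bins / 2^P) + 1, bins)
    hist[b] <- hist[b] + 1
  }
  hist / sum(hist)
}

# symmetric normalized co-occurrence table by explicit pair enumeration
oracle_glcm_table <- function(lev, dr, dc, n_levels) {
  h <- nrow(lev); w <- ncol(lev)
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        counts[lev[r, c], lev[r2, c2]] <- counts[lev[r, c], lev[r2, c2]] + 1
        counts[lev[r2, c2], lev[r, c]] <- counts[lev[r2, c2], lev[r, c]] + 1
      }
    }
  }
  counts / sum(counts)
}

# confusion tally by explicit loop
oracle_confusion <- function(actual, predicted, classes) {
  k <- length(classes)
  m <- matrix(0L, k, k, dimnames = list(classes, classes))
  for (i in seq_along(actual)) {
    a <- match(actual[i], classes); p <- match(predicted[i], classes)
    m[a, p] <- m[a, p] + 1L
  }
  m
}

# AUC as the Mann-Whitney pair statistic (ties count one half)
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# two well-separated Gaussian classes (centre distance 10 sigma)
gaussian_fixture <- function(n = 200, k = 2, d = 2, seed = 42) {
  withr::with_seed(seed, {
    centers <- matrix(10 * seq_len(k), k, d)
    x <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(stats::rnorm(n / k * d, mean = centers[i, 1], sd = 1),
             ncol = d)
    }))
    list(x = x, labels = factor(rep(letters[seq_len(k)], each = n / k)))
  })
}
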