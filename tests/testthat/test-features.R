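test_that("LBP histogram has the published length and unit mass", {
  set.seed(41)
  x <- matrix(runif(20 * 20, 0, 255), 20)
  f <- lbp_features(make_roi(x))
  expect_length(f, 203)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_true(all(attr(f, "blocks") == "lbp"))
})

test_that("a constant ROI yields the all-ones LBP code", {
  f <- lbp_features(make_roi(matrix(100, 10, 10)), bins = 256)
  expect_equal(unname(f[256]), 1)           # code 2^8 - 1 = 255: s(0) = 1
  expect_equal(sum(f[-256]), 0)
  f203 <- lbp_features(make_roi(matrix(100, 10, 10)))
  expect_equal(unname(f203[203]), 1)
})

test_that("LBP codes match the bit-by-bit oracle", {
  set.seed(42)
  # 5 x 5 ROI with distinct values: each interior code checked bit by bit
  x <- matrix(sample(1:25 * 7), 5, 5)
  f <- lbp_features(make_roi(x), bins = 256)
  codes <- as.vector(outer(2:4, 2:4,
                           Vectorize(function(r, c) oracle_lbp_code(x, r, c))))
  expect_equal(as.numeric(f), tabulate(codes + 1, 256) / 9)

  for (i in 1:3) {
    y <- matrix(runif(12 * 15, 0, 255), 12)
    expect_equal(as.numeric(lbp_features(make_roi(y))),
                 oracle_lbp_hist(y), tolerance = 1e-12)
  }
})

test_that("undersized ROIs are rejected for LBP", {
  expect_error(lbp_features(make_roi(matrix(1:32, 2, 16))), "smaller")
})

test_that("co-occurrence features have length 13 with sane ranges", {
  set.seed(43)
  x <- matrix(runif(24 * 24, 0, 255), 24)
  f <- glcm_features(make_roi(x))
  expect_length(f, 13)
  expect_true(all(is.finite(f)))
  expect_gt(f["glcm_1"], 0)                  # energy in (0, 1]
  expect_lte(f["glcm_1"], 1)
  expect_gte(f["glcm_9"], 0)                 # entropy >= 0
})

test_that("a constant ROI gives the degenerate single-cell table", {
  expect_warning(f <- glcm_features(make_roi(matrix(9, 16, 16))),
                 "degenerate")
  expect_equal(unname(f[c(1, 2, 9)]), c(1, 0, 0))  # energy, contrast, entropy
})

test_that("co-occurrence tables match pair enumeration on a checkerboard", {
  cb <- matrix(0, 4, 4)                     # two-level checkerboard
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 255
  lev <- (cb > 0) + 1L
  mask <- matrix(TRUE, 4, 4)
  impl <- endodiag:::glcm_table(lev, mask, 0L, 1L, 2L)
  orac <- oracle_glcm_table(lev, 0L, 1L, 2L)
  expect_equal(impl, orac)
  # horizontal neighbours always differ by one level: contrast = 1
  expect_equal(sum(impl * (row(impl) - col(impl))^2), 1)

  set.seed(44)
  for (i in 1:3) {
    x <- matrix(sample(0:5, 64, replace = TRUE), 8, 8)
    lev <- x + 1L
    m8 <- matrix(TRUE, 8, 8)
    for (off in list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))) {
      expect_equal(endodiag:::glcm_table(lev, m8, off[1], off[2], 6L),
                   oracle_glcm_table(lev, off[1], off[2], 6L))
    }
  }
})

test_that("co-occurrence features are shift-invariant in the exact-level regime", {
  set.seed(45)
  x <- matrix(sample(seq(10, 90, by = 10), 100, replace = TRUE), 10)
  n_distinct <- length(unique(as.numeric(x)))
  f1 <- glcm_features(make_roi(x), n_levels = n_distinct)
  f2 <- glcm_features(make_roi(x + 37.5), n_levels = n_distinct)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-12)
})

test_that("the fuzzy colour histogram has 16 bins summing to one", {
  set.seed(46)
  img <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  f <- fch_features(make_roi(img))
  expect_length(f, 16)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_true(all(f > 0))                   # fuzzy mass reaches every bin
})

test_that("crisp colour assignment counts nearest centres exactly", {
  solid <- array(0, c(16, 16, 3))
  solid[, , 1] <- 200; solid[, , 2] <- 40; solid[, , 3] <- 40
  f <- fch_features(make_roi(solid), mode = "crisp")
  expect_equal(sum(f == 1), 1)
  expect_equal(sum(f), 1)

  half <- array(0, c(16, 16, 3))
  half[1:8, , 1] <- 255                     # top half pure red
  half[9:16, , 3] <- 255                    # bottom half pure blue
  f2 <- fch_features(make_roi(half), mode = "crisp")
  expect_equal(sort(as.numeric(f2), decreasing = TRUE)[1:2], c(0.5, 0.5))
  expect_equal(sum(f2 > 0), 2)
})

test_that("grayscale input to the colour histogram is an error", {
  expect_error(fch_features(make_roi(matrix(1, 16, 16))), "RGB")
})

test_that("fusion concatenates blocks to the published 232 layout", {
  set.seed(47)
  img <- array(runif(24 * 24 * 3, 0, 255), c(24, 24, 3))
  roi <- make_roi(img)
  lbp <- lbp_features(roi); glcm <- glcm_features(roi)
  fch <- fch_features(roi)
  fused <- fuse_features(lbp, glcm, fch)
  expect_length(fused, 232)
  expect_equal(attr(fused, "blocks"),
               rep(c("lbp", "glcm", "fch"), c(203, 13, 16)))
  expect_equal(as.numeric(fused),
               c(as.numeric(lbp), as.numeric(glcm), as.numeric(fch)))

  expect_equal(as.numeric(fuse_features(glcm)), as.numeric(glcm))
  expect_error(fuse_features(list()), "at least one")

  a <- feature_vector(runif(3), "lbp")
  b <- feature_vector(runif(2), "glcm")
  cc <- feature_vector(runif(4), "fch")
  expect_equal(as.numeric(fuse_features(a, fuse_features(b, cc))),
               as.numeric(fuse_features(fuse_features(a, b), cc)))
})

test_that("the handcrafted pipeline is deterministic", {
  set.seed(48)
  img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  roi <- make_roi(img)
  v1 <- fuse_features(lbp_features(roi), glcm_features(roi),
                      fch_features(roi))
  v2 <- fuse_features(lbp_features(roi), glcm_features(roi),
                      fch_features(roi))
  expect_identical(as.numeric(v1), as.numeric(v2))
})

test_that("deep extraction honours the declared width and determinism", {
  set.seed(49)
  img1 <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  img2 <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))

  ex <- fallback_extractor(width = 4096, seed = 7)
  d1 <- deep_extract(img1, ex)
  expect_length(d1, 4096)
  expect_identical(as.numeric(d1),
                   as.numeric(deep_extract(img1, fallback_extractor(4096, 7))))
  expect_true(any(as.numeric(d1) !=
                    as.numeric(deep_extract(img2, ex))))

  liar <- structure(list(width = 32L, fn = function(image) numeric(8)),
                    class = "feature_extractor")
  expect_error(deep_extract(img1, liar), "contract")
})

test_that("deep + handcrafted fusion yields the hybrid layout", {
  set.seed(50)
  img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  roi <- make_roi(img)
  hand <- fuse_features(lbp_features(roi), glcm_features(roi),
                        fch_features(roi))
  small <- deep_extract(img, fallback_extractor(width = 8, seed = 1))
  hyb <- fuse_deep(small, hand)
  expect_length(hyb, 240)
  expect_equal(unique(attr(hyb, "blocks")), c("deep", "lbp", "glcm", "fch"))

  incomplete <- fuse_features(lbp_features(roi), glcm_features(roi))
  expect_error(fuse_deep(small, incomplete), "missing")
})

test_that("masked ROIs restrict features to lesion pixels", {
  d <- generate_disc(size = 64, radius = 15, fg = 180, bg = 40)
  roi <- make_roi(d$gray, d$mask)
  expect_warning(f <- glcm_features(roi), "degenerate")  # single level inside
  expect_equal(unname(f["glcm_1"]), 1)
  expect_error(make_roi(d$gray, matrix(FALSE, 64, 64)))
})
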