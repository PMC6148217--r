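test_that("CIELUV conversion matches the colourimetric reference points", {
  # expected values computed independently from the CIE formulas
  # (sRGB -> linear -> XYZ (D65) -> L*u*v*)
  px <- function(rgb) array(rep(rgb, each = 1), c(1, 1, 3))
  black <- to_cieluv(px(c(0, 0, 0)))
  expect_equal(as.vector(black), c(0, 0, 0), tolerance = 1e-6)
  white <- to_cieluv(px(c(1, 1, 1)))
  expect_equal(white[1, 1, 1], 100, tolerance = 1e-4)
  expect_equal(as.vector(white[1, 1, 2:3]), c(0, 0), tolerance = 1e-6)
  grey <- to_cieluv(array(0.42, c(3, 2, 3)))
  expect_true(all(abs(grey[, , 2:3]) < 1e-6))
  blue_grey <- to_cieluv(px(c(0.2, 0.4, 0.6)))
  expect_equal(as.vector(blue_grey), c(42.0081, -20.2486, -47.5548),
               tolerance = 0.02)
  red <- to_cieluv(px(c(1, 0, 0)))
  expect_equal(as.vector(red), c(53.2408, 175.015, 37.7564),
               tolerance = 0.02)
})

test_that("CIELUV conversion accepts 8-bit input and rejects wrong channels", {
  a <- to_cieluv(array(c(51, 102, 153), c(1, 1, 3)))
  b <- to_cieluv(array(c(0.2, 0.4, 0.6), c(1, 1, 3)))
  expect_equal(a, b, tolerance = 1e-6)
  expect_error(to_cieluv(array(0, c(4, 4, 2))), "3-channel")
  expect_error(to_cieluv(matrix(0, 4, 4)), "3-channel")
})

test_that("single-level Haar transform of a 2x2 checkerboard matches hand values", {
  # orthonormal transform computed by hand: rows then columns with
  # (sum, difference)/sqrt(2)
  x <- matrix(c(1, 0, 0, 1), 2, 2)
  dec <- pluckseg:::haar_dwt2(x)
  expect_equal(dec$a[1, 1], 1)
  expect_equal(dec$h[1, 1], 0)
  expect_equal(dec$v[1, 1], 0)
  expect_equal(dec$d[1, 1], 1)
  # constant input: all details vanish, approximation doubles
  dec2 <- pluckseg:::haar_dwt2(matrix(3, 4, 4))
  expect_true(all(abs(c(dec2$h, dec2$v, dec2$d)) < 1e-12))
  expect_true(all(abs(dec2$a - 6) < 1e-12))
})

test_that("feature grid has channels x 4 x levels features and ceil-sized grid", {
  img <- array(runif(45 * 26 * 3), c(45, 26, 3))
  for (lev in 1:3) for (f in c(1, 4, 20)) {
    fg <- haar_feature_grid(img, decomposition_config(levels = lev,
                                                      subsample_factor = f))
    expect_equal(dim(fg), c(ceiling(45 / f), ceiling(26 / f), 3 * 4 * lev))
    expect_true(all(is.finite(fg)))
  }
  # factor 1 is the identity on spatial dimensions
  fg1 <- haar_feature_grid(img, decomposition_config(subsample_factor = 1))
  expect_equal(dim(fg1)[1:2], c(45, 26))
  expect_equal(dim(fg1)[3], 36)
})

test_that("constant channels give exactly zero squared detail features", {
  img <- array(rep(c(0.3, 0.5, 0.7), each = 32 * 16), c(32, 16, 3))
  fg <- haar_feature_grid(img, decomposition_config(subsample_factor = 2))
  detail <- grep("horiz|vert|diag", dimnames(fg)[[3]])
  expect_true(all(fg[, , detail] == 0))
  expect_true(all(fg[, , -detail] != 0))
})

test_that("squared detail features are nonnegative everywhere", {
  set.seed(9)
  img <- array(runif(40 * 24 * 3), c(40, 24, 3))
  fg <- haar_feature_grid(img, decomposition_config(subsample_factor = 3))
  detail <- grep("horiz|vert|diag", dimnames(fg)[[3]])
  expect_true(all(fg[, , detail] >= 0))
})

test_that("too-small images raise a decomposition-depth error", {
  expect_error(haar_feature_grid(array(0.5, c(7, 32, 3)),
                                 decomposition_config(levels = 3)),
               "too small")
  expect_silent(haar_feature_grid(array(0.5, c(8, 32, 3)),
                                  decomposition_config(levels = 3)))
})

test_that("translating by one subsample stride shifts the grid by one cell", {
  # exact when the stride is a multiple of the coarsest Haar block
  set.seed(4)
  base <- array(runif(64 * 48 * 3), c(64, 48, 3))
  f <- 4; lev <- 2 # stride 4 = 2^levels
  shifted <- base
  shifted[(f + 1):64, (f + 1):48, ] <- base[1:(64 - f), 1:(48 - f), ]
  g1 <- haar_feature_grid(base, decomposition_config(lev, f))
  g2 <- haar_feature_grid(shifted, decomposition_config(lev, f))
  inner_r <- 3:(dim(g1)[1] - 3); inner_c <- 3:(dim(g1)[2] - 3)
  expect_equal(g2[inner_r + 1, inner_c + 1, ],
               g1[inner_r, inner_c, ], tolerance = 1e-10)
})

test_that("label sub-sampling keeps the top-left cell of each block", {
  lab <- matrix(seq_len(20 * 12), 20, 12)
  s <- subsample_labels(lab, 4)
  expect_equal(dim(s), c(5, 3))
  expect_equal(s[1, 1], lab[1, 1])
  expect_equal(s[2, 2], lab[5, 5])
})
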