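#' Local appearance feature configuration
#'
#' Controls the Haar-wavelet appearance pipeline: the colour image is
#' converted to CIELUV, each of the three components is decomposed with a
#' multi-level 2-D Haar wavelet transform, detail coefficients are squared
#' (approximation left as-is), every coefficient map is rescaled back to the
#' image resolution, and the stack is sub-sampled on a rectilinear grid.
#' Defaults give `3 channels x 4 coefficient kinds x 3 levels = 36` features.
#'
#' @param levels decomposition depth (>= 1, default 3).
#' @param subsample_factor grid stride in pixels (default 20); the grid keeps
#'   the top-left pixel of every `factor x factor` block, so the grid is
#'   `ceiling(H/factor) x ceiling(W/factor)`.
#' @param square_details square the detail coefficient maps (default TRUE).
#' @return an object of class `"decomposition_config"`.
#' @export
decomposition_config <- function(levels = 3, subsample_factor = 20,
                                 square_details = TRUE) {
  stopifnot(levels >= 1, subsample_factor >= 1)
  structure(list(levels = as.integer(levels),
                 subsample_factor = as.integer(subsample_factor),
                 square_details = isTRUE(square_details)),
            class = "decomposition_config")
}

#' Convert an sRGB image to CIELUV
#'
#' @param image `H x W x 3` array of sRGB values, either in `[0, 1]` or
#'   8-bit `[0, 255]`.
#' @return `H x W x 3` array holding the L*, u*, v* components (CIE 1976,
#'   D65 white point); L* ranges over `[0, 100]`.
#' @export
to_cieluv <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("expected a 3-channel image, got ",
         paste(dim(image), collapse = "x"))
  d <- dim(image)
  m <- matrix(image, d[1] * d[2], 3)
  if (max(m) > 1 + 1e-9) m <- m / 255
  luv <- grDevices::convertColor(m, from = "sRGB", to = "Luv")
  array(luv, d)
}

# One level of the separable orthonormal 2-D Haar transform. Odd-sized
# inputs are symmetrically padded by replicating the last row/column.
# Returns approximation `a` and detail maps: `h` (column-pair differences,
# responds to vertical edges), `v` (row-pair differences, horizontal edges),
# `d` (diagonal).
haar_dwt2 <- function(x) {
  if (nrow(x) %% 2 == 1) x <- rbind(x, x[nrow(x), ])
  if (ncol(x) %% 2 == 1) x <- cbind(x, x[, ncol(x)])
  ro <- seq(1, nrow(x), 2)
  lo <- (x[ro, , drop = FALSE] + x[ro + 1, , drop = FALSE]) / sqrt(2)
  hi <- (x[ro, , drop = FALSE] - x[ro + 1, , drop = FALSE]) / sqrt(2)
  co <- seq(1, ncol(x), 2)
  list(a = (lo[, co, drop = FALSE] + lo[, co + 1, drop = FALSE]) / sqrt(2),
       h = (lo[, co, drop = FALSE] - lo[, co + 1, drop = FALSE]) / sqrt(2),
       v = (hi[, co, drop = FALSE] + hi[, co + 1, drop = FALSE]) / sqrt(2),
       d = (hi[, co, drop = FALSE] - hi[, co + 1, drop = FALSE]) / sqrt(2))
}

# Nearest-neighbour upscaling of a level-`lev` coefficient map back to the
# source resolution: each coefficient covers a 2^lev x 2^lev pixel block.
upscale_coeff <- function(m, lev, H, W) {
  s <- 2^lev
  m[ceiling(seq_len(H) / s), ceiling(seq_len(W) / s), drop = FALSE]
}

#' Haar-wavelet appearance feature grid
#'
#' @param luv `H x W x 3` array (any 3-channel real raster; typically the
#'   output of [to_cieluv()]).
#' @param config a [decomposition_config()].
#' @return an object of class `"feature_grid"`: an `h x w x F` array with
#'   attributes `subsample_factor` and `source_shape`; the third dimension
#'   is named `channel.levelL.kind`. `F = 3 x 4 x levels` (36 at defaults).
#' @export
#' @examples
#' img <- array(runif(32 * 16 * 3), c(32, 16, 3))
#' fg <- haar_feature_grid(img, decomposition_config(subsample_factor = 4))
#' dim(fg)   # 8 4 36
haar_feature_grid <- function(luv, config = decomposition_config()) {
  if (length(dim(luv)) != 3 || dim(luv)[3] != 3)
    stop("expected a 3-channel raster")
  if (!all(is.finite(luv))) stop("raster contains non-finite values")
  H <- dim(luv)[1]; W <- dim(luv)[2]
  if (min(H, W) < 2^config$levels)
    stop("image of size ", H, "x", W, " is too small for ", config$levels,
         " decomposition levels (needs at least ", 2^config$levels,
         " pixels in each dimension)")
  f <- config$subsample_factor
  ri <- seq(1, H, f); ci <- seq(1, W, f)
  kinds <- c("approx", "horiz", "vert", "diag")
  channels <- c("L", "u", "v")
  Fn <- 3 * 4 * config$levels
  out <- array(NA_real_, c(length(ri), length(ci), Fn))
  nm <- character(Fn)
  i <- 0
  for (ch in 1:3) {
    x <- luv[, , ch]
    for (lev in seq_len(config$levels)) {
      dec <- haar_dwt2(x)
      maps <- list(dec$a, dec$h, dec$v, dec$d)
      for (kk in 1:4) {
        m <- maps[[kk]]
        if (kk > 1 && config$square_details) m <- m^2
        i <- i + 1
        out[, , i] <- upscale_coeff(m, lev, H, W)[ri, ci, drop = FALSE]
        nm[i] <- paste0(channels[ch], ".level", lev, ".", kinds[kk])
      }
      x <- dec$a
    }
  }
  dimnames(out) <- list(NULL, NULL, nm)
  structure(out, subsample_factor = f, source_shape = c(H, W),
            class = c("feature_grid", "array"))
}

#' Sub-sample a full-resolution label image onto the feature grid
#'
#' Keeps the top-left pixel of every `factor x factor` block, matching the
#' alignment used by [haar_feature_grid()].
#'
#' @param labels integer matrix of per-pixel labels (0 = background).
#' @param factor the grid stride.
#' @return integer matrix of grid-cell labels.
#' @export
subsample_labels <- function(labels, factor) {
  labels[seq(1, nrow(labels), factor), seq(1, ncol(labels), factor),
         drop = FALSE]
}

#' Compute the appearance feature grid of a colour image
#'
#' Convenience wrapper: [to_cieluv()] then [haar_feature_grid()].
#'
#' @inheritParams to_cieluv
#' @inheritParams haar_feature_grid
#' @return a `feature_grid`.
#' @export
appearance_features <- function(image, config = decomposition_config()) {
  haar_feature_grid(to_cieluv(image), config)
}
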