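#' Star-shaped context stencil
#'
#' Context features are class probabilities sampled at a sparse set of
#' positions relative to the cell being classified. The stencil is a star:
#' `n_rays` equally spaced rays (the first pointing along increasing column
#' index), each carrying one point per radius, plus the centre. The default
#' geometry -- 10 rays and 9 roughly log-spaced radii -- gives 91 points
#' (90 surrounding points plus the centre), so with K = 5 classes a stencil
#' query yields 455 context features.
#'
#' @param n_rays number of equally spaced rays (>= 1).
#' @param radii strictly increasing positive radii, in grid cells. May be
#'   empty, giving the centre-only stencil.
#' @return an object of class `"stencil"`: an `n x 2` integer matrix of
#'   `(row, col)` offsets whose first row is the centre `(0, 0)`.
#' @export
#' @examples
#' nrow(star_stencil())            # 91
#' star_stencil(4, 1)              # centre plus the 4 axis neighbours
star_stencil <- function(n_rays = 10,
                         radii = c(2, 4, 7, 11, 16, 22, 29, 37, 46)) {
  stopifnot(n_rays >= 1)
  if (length(radii)) {
    if (any(radii <= 0) || any(diff(radii) <= 0))
      stop("radii must be positive and strictly increasing")
  }
  theta <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  off <- rbind(c(0L, 0L))
  for (r in radii)
    off <- rbind(off, cbind(round(r * sin(theta)), round(r * cos(theta))))
  storage.mode(off) <- "integer"
  if (anyDuplicated(off))
    stop("stencil geometry error: offsets collide after rounding; ",
         "adjust n_rays or radii")
  dimnames(off) <- list(NULL, c("row", "col"))
  structure(off, class = c("stencil", "matrix"))
}

#' @export
print.stencil <- function(x, ...) {
  cat("star stencil with", nrow(x), "points (centre included)\n")
  cat("reach:", max(abs(x)), "cells\n")
  invisible(x)
}

#' Stencil context features at a location
#'
#' Samples the K class probabilities of `map` at every stencil point centred
#' on `location`, concatenated in stencil order (classes contiguous within
#' each point). Points falling outside the grid or on background yield the
#' uniform padding distribution.
#'
#' @param map a [prob_map].
#' @param location `(row, col)` of a foreground cell.
#' @param stencil a [star_stencil].
#' @return numeric vector of length `nrow(stencil) * K`.
#' @export
stencil_context <- function(map, location, stencil = star_stencil()) {
  stopifnot(inherits(map, "prob_map"))
  loc <- matrix(as.integer(location), 1, 2)
  if (!map$foreground[loc[1, 1], loc[1, 2]])
    stop("location (", loc[1, 1], ",", loc[1, 2], ") is not a foreground cell")
  drop(stencil_context_matrix(map, loc, stencil))
}

# Vectorised stencil context: one row per query location.
stencil_context_matrix <- function(map, locations, stencil) {
  d <- dim(map$probs)
  h <- d[1]; w <- d[2]; K <- d[3]
  n <- nrow(locations)
  S <- nrow(stencil)
  pv <- as.vector(map$probs)
  fg <- map$foreground
  out <- matrix(1 / K, n, S * K)
  for (s in seq_len(S)) {
    rr <- locations[, 1] + stencil[s, 1]
    cc <- locations[, 2] + stencil[s, 2]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    ok[ok] <- fg[cbind(rr[ok], cc[ok])]
    if (!any(ok)) next
    base <- (cc[ok] - 1) * h + rr[ok]
    for (k in seq_len(K))
      out[ok, (s - 1) * K + k] <- pv[(k - 1) * h * w + base]
  }
  out
}

#' Integral context features at a location
#'
#' Two aggregate summaries of a probability map, designed for objects hung
#' vertically in a consistent pose: (a) the mean class probabilities over the
#' foreground cells of the query's row, telling the next classifier which
#' classes occur at that height; and (b) the mean class probabilities over
#' the whole foreground, reflecting what proportion of the visible object
#' each class covers.
#'
#' @inheritParams stencil_context
#' @return numeric vector of length `2 * K`: row block then image block.
#' @export
integral_context <- function(map, location) {
  stopifnot(inherits(map, "prob_map"))
  loc <- as.integer(location)
  if (!map$foreground[loc[1], loc[2]])
    stop("location (", loc[1], ",", loc[2], ") is not a foreground cell")
  s <- integral_summary(map)
  c(s$row_means[loc[1], ], s$image_mean)
}

# Precomputed row-wise and image-wise foreground means, one row per grid row.
# Rows with no foreground hold NA (they can never be queried).
integral_summary <- function(map) {
  d <- dim(map$probs)
  fg <- map$foreground
  nfg <- rowSums(fg)
  if (sum(nfg) == 0) stop("degenerate mask: probability map has no foreground")
  K <- d[3]
  rm <- matrix(NA_real_, d[1], K)
  tot <- numeric(K)
  for (k in seq_len(K)) {
    pk <- map$probs[, , k]
    sk <- rowSums(pk * fg)
    rm[, k] <- ifelse(nfg > 0, sk / nfg, NA_real_)
    tot[k] <- sum(sk)
  }
  list(row_means = rm, image_mean = tot / sum(nfg))
}

integral_context_matrix <- function(map, locations) {
  s <- integral_summary(map)
  cbind(s$row_means[locations[, 1], , drop = FALSE],
        matrix(s$image_mean, nrow(locations), length(s$image_mean),
               byrow = TRUE))
}
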