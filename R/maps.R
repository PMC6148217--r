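#' Label maps and probability maps
#'
#' The package works on a rectilinear grid of cells (sub-sampled pixels).
#' A `label_map` stores one integer class per foreground cell (0 denotes
#' background); a `prob_map` stores a length-K probability distribution per
#' cell. Background cells of a `prob_map` hold the *padding distribution* --
#' uniform over the K classes -- expressing maximal label uncertainty outside
#' the object. Grids are indexed `[row, col]` with row 1 at the top.
#'
#' @param labels integer matrix, values in `0..K` (0 = background).
#' @param K number of classes; defaults to `length(class_names)` or
#'   `max(labels)` (at least 2).
#' @param class_names character vector of K class names.
#' @param id optional identifier used in atlas provenance and reports.
#' @return `label_map()` returns an object of class `"label_map"` with fields
#'   `labels`, `foreground`, `class_names`, `id`.
#' @export
#' @examples
#' lm <- label_map(matrix(c(0, 1, 2, 2), 2, 2), K = 5)
#' lm$foreground
label_map <- function(labels, K = NULL, class_names = NULL, id = NULL) {
  stopifnot(is.matrix(labels))
  labels <- round(labels)
  storage.mode(labels) <- "integer"
  if (is.null(K)) K <- if (!is.null(class_names)) length(class_names) else
    max(2L, max(labels))
  if (any(labels < 0 | labels > K))
    stop("label values must lie in 0..K (K = ", K, ")")
  if (is.null(class_names)) class_names <- default_class_names(K)
  if (length(class_names) != K) stop("class_names must have length K")
  structure(list(labels = labels, foreground = labels > 0,
                 class_names = class_names, id = id),
            class = "label_map")
}

default_class_names <- function(K) {
  if (K == 5) c("upper", "heart", "lungs", "diaphragm", "liver")
  else paste0("class", seq_len(K))
}

#' @rdname label_map
#' @param probs `h x w x K` numeric array of per-cell class probabilities.
#' @param foreground logical `h x w` matrix; `NULL` means all cells.
#' @param normalize if `TRUE`, foreground distributions are renormalised to
#'   sum to one (they must already be within 1e-6 of that).
#' @export
prob_map <- function(probs, foreground = NULL, class_names = NULL,
                     normalize = FALSE) {
  stopifnot(is.array(probs), length(dim(probs)) == 3)
  d <- dim(probs)
  K <- d[3]
  if (K < 2) stop("a probability map needs at least 2 classes")
  if (is.null(foreground)) foreground <- matrix(TRUE, d[1], d[2])
  stopifnot(is.logical(foreground), all(dim(foreground) == d[1:2]))
  if (is.null(class_names)) class_names <- default_class_names(K)
  if (length(class_names) != K) stop("class_names must have length K")
  pm <- matrix(probs, d[1] * d[2], K)
  fg <- as.vector(foreground)
  if (any(fg)) {
    if (any(pm[fg, ] < -1e-9)) stop("negative probabilities on foreground")
    s <- rowSums(pm[fg, , drop = FALSE])
    if (any(abs(s - 1) > 1e-6)) {
      if (normalize) pm[fg, ] <- pm[fg, , drop = FALSE] / s
      else stop("foreground distributions must sum to 1 (max deviation ",
                format(max(abs(s - 1))), ")")
    }
  }
  pm[!fg, ] <- 1 / K # padding distribution
  structure(list(probs = array(pm, d), foreground = foreground,
                 class_names = class_names),
            class = "prob_map")
}

padding_distribution <- function(K) rep(1 / K, K)

n_classes <- function(x) {
  if (inherits(x, "label_map")) length(x$class_names)
  else dim(x$probs)[3]
}

grid_dim <- function(x) {
  if (inherits(x, "label_map")) dim(x$labels) else dim(x$probs)[1:2]
}

check_same_grid <- function(a, b) {
  if (!all(grid_dim(a) == grid_dim(b)) || n_classes(a) != n_classes(b))
    stop("grids are not compatible: ", paste(grid_dim(a), collapse = "x"),
         "/K=", n_classes(a), " vs ", paste(grid_dim(b), collapse = "x"),
         "/K=", n_classes(b))
  invisible(TRUE)
}

#' Hard class assignment from a probability map
#'
#' Assigns every foreground cell the class with the highest probability,
#' breaking ties in favour of the lowest class index; background stays 0.
#'
#' @param probs a [prob_map].
#' @return a [label_map] on the same grid.
#' @export
argmax_labels <- function(probs) {
  stopifnot(inherits(probs, "prob_map"))
  d <- dim(probs$probs)
  m <- matrix(probs$probs, d[1] * d[2], d[3])
  lab <- max.col(m, ties.method = "first")
  lab[!as.vector(probs$foreground)] <- 0L
  label_map(matrix(as.integer(lab), d[1], d[2]), K = d[3],
            class_names = probs$class_names)
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat("label map ", d[1], "x", d[2], ", K = ", n_classes(x),
      " (", paste(x$class_names, collapse = ", "), ")\n", sep = "")
  cat("foreground cells:", sum(x$foreground), "\n")
  tab <- tabulate(x$labels[x$foreground], nbins = n_classes(x))
  names(tab) <- x$class_names
  print(tab)
  invisible(x)
}

#' @export
print.prob_map <- function(x, ...) {
  d <- dim(x$probs)
  cat("probability map ", d[1], "x", d[2], ", K = ", d[3],
      " (", paste(x$class_names, collapse = ", "), ")\n", sep = "")
  cat("foreground cells:", sum(x$foreground), "\n")
  mass <- apply(matrix(x$probs, d[1] * d[2], d[3])[x$foreground, , drop = FALSE],
                2, mean)
  names(mass) <- x$class_names
  cat("mean foreground class probabilities:\n")
  print(round(mass, 4))
  invisible(x)
}

#' @export
plot.label_map <- function(x, col = NULL, ...) {
  K <- n_classes(x)
  if (is.null(col)) col <- c("grey15", grDevices::hcl.colors(K, "Dark 3"))
  img <- t(x$labels[nrow(x$labels):1, , drop = FALSE])
  graphics::image(img, col = col, zlim = c(0, K), axes = FALSE, asp = nrow(x$labels) / ncol(x$labels), ...)
  invisible(x)
}

# Nearest-neighbour resampling of a probability map onto a new grid shape.
resample_prob_map <- function(pm, new_dim, foreground = NULL) {
  d <- dim(pm$probs)
  ri <- pmin(d[1], pmax(1L, round(seq_len(new_dim[1]) * d[1] / new_dim[1])))
  ci <- pmin(d[2], pmax(1L, round(seq_len(new_dim[2]) * d[2] / new_dim[2])))
  probs <- pm$probs[ri, ci, , drop = FALSE]
  fg <- if (is.null(foreground)) pm$foreground[ri, ci, drop = FALSE] else foreground
  prob_map(probs, fg, pm$class_names, normalize = TRUE)
}
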