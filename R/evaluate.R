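#' Per-class Dice coefficients
#'
#' For each class c, `2 |X n Y| / (|X| + |Y|)` where X is the reference
#' region and Y the predicted region. Classes with an empty reference
#' region are returned as `NA` and are excluded from downstream medians
#' (an organ that is genuinely absent cannot be scored).
#'
#' @param reference,predicted [label_map]s on the same grid.
#' @return named numeric vector of length K (NA where the class is absent
#'   from the reference).
#' @export
#' @examples
#' a <- label_map(matrix(c(1, 1, 2, 2), 2), K = 2)
#' dice(a, a)   # both 1
dice <- function(reference, predicted) {
  stopifnot(inherits(reference, "label_map"), inherits(predicted, "label_map"))
  check_same_grid(reference, predicted)
  K <- n_classes(reference)
  out <- vapply(seq_len(K), function(k) {
    nref <- sum(reference$labels == k)
    if (nref == 0) return(NA_real_)
    npred <- sum(predicted$labels == k)
    2 * sum(reference$labels == k & predicted$labels == k) / (nref + npred)
  }, numeric(1))
  names(out) <- reference$class_names
  out
}

#' Mean quadratic (Brier-type) score of a probabilistic segmentation
#'
#' The proper scoring rule `2 r_true - sum_c r_c^2` averaged over the
#' reference foreground, where `r` is the predicted distribution at a cell
#' and `r_true` its probability on the ground-truth class. Equals 1 for a
#' confident correct prediction, `2/K - 1/K` for a uniform one, and -1 for
#' a confident wrong one.
#'
#' @param probs a [prob_map].
#' @param reference a [label_map] on the same grid.
#' @return a number in `[-1, 1]`.
#' @export
quadratic_score <- function(probs, reference) {
  stopifnot(inherits(probs, "prob_map"), inherits(reference, "label_map"))
  check_same_grid(probs, reference)
  d <- dim(probs$probs)
  cells <- which(reference$foreground)
  if (!length(cells)) stop("degenerate mask: reference has no foreground")
  m <- matrix(probs$probs, d[1] * d[2], d[3])[cells, , drop = FALSE]
  r_true <- m[cbind(seq_along(cells), reference$labels[cells])]
  mean(2 * r_true - rowSums(m^2))
}

#' Pixel-level confusion matrix
#'
#' Entry `(c, c')` counts the cells whose reference label is c and predicted
#' label c', over cells that are foreground in both maps. Rows are ground
#' truth, columns are predictions.
#'
#' @inheritParams dice
#' @return `K x K` integer matrix with class names on both dimensions.
#' @export
confusion <- function(reference, predicted) {
  stopifnot(inherits(reference, "label_map"), inherits(predicted, "label_map"))
  check_same_grid(reference, predicted)
  K <- n_classes(reference)
  keep <- reference$foreground & predicted$foreground
  tab <- table(factor(reference$labels[keep], levels = seq_len(K)),
               factor(predicted$labels[keep], levels = seq_len(K)))
  m <- matrix(as.integer(tab), K, K,
              dimnames = list(truth = reference$class_names,
                              predicted = reference$class_names))
  m
}

#' Cross-validated evaluation of an auto-context variant
#'
#' Randomly assigns images to `folds` subsets (deterministically given
#' `seed`), trains on all but one subset and evaluates on the held-out
#' subset. Aggregation follows the organ-level and pixel-level protocols:
#' per-class medians of Dice scores over images where the organ is present
#' in the ground truth, their mean (`class_average`), the median over
#' images of the per-image mean quadratic score, and the summed confusion
#' matrix.
#'
#' @param data a `pluck_dataset` or list of `pluck_sample`s.
#' @param variant a [variant_config()]; its `seed` is re-derived per fold.
#' @param folds number of folds (default 10).
#' @param seed seed for the fold assignment and per-fold training.
#' @param features a [decomposition_config()] (default: images already at
#'   grid resolution).
#' @return an object of class `"autocontext_cv"`: a list with `dice`
#'   (long-format per image and class), `per_class_median`,
#'   `class_average`, `quadratic` (per image), `median_quadratic`,
#'   `confusion`, `fold` assignment and `accuracy` (final-iteration pixel
#'   accuracy vs. the prior-atlas arg-max baseline).
#' @export
cross_validate <- function(data, variant = variant_config(), folds = 10,
                           seed = 1L,
                           features = decomposition_config(subsample_factor = 1)) {
  samples <- if (inherits(data, "pluck_dataset")) data$samples else data
  n <- length(samples)
  stopifnot(n >= folds, folds >= 2)
  fold <- integer(n)
  fold[with_seed(sub_seed(seed, "folds"), sample.int(n))] <-
    rep(seq_len(folds), length.out = n)
  ids <- vapply(seq_len(n), function(j) {
    id <- samples[[j]]$labels$id
    if (is.null(id)) sprintf("img%04d", j) else as.character(id)
  }, character(1))
  K <- n_classes(samples[[1]]$labels)
  class_names <- samples[[1]]$labels$class_names
  dice_rows <- list(); quad <- numeric(n); acc <- numeric(n)
  base_acc <- numeric(n)
  conf <- matrix(0L, K, K, dimnames = list(truth = class_names,
                                           predicted = class_names))
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    cfg <- variant
    cfg$seed <- sub_seed(seed, "fold", f)
    model <- autocontext(samples[tr], variant = cfg, features = features,
                         allow_missing = TRUE)
    for (j in te) {
      truth <- samples[[j]]$labels
      pred <- predict(model, samples[[j]])
      lab <- argmax_labels(pred)
      dj <- dice(truth, lab)
      dice_rows[[length(dice_rows) + 1]] <-
        data.frame(image = ids[j], class = class_names,
                   dice = unname(dj), fold = f)
      quad[j] <- quadratic_score(pred, truth)
      conf <- conf + confusion(truth, lab)
      fg <- truth$foreground
      acc[j] <- mean(lab$labels[fg] == truth$labels[fg])
      base <- resample_prob_map(model$prior, dim(truth$labels), fg)
      base_acc[j] <- mean(argmax_labels(base)$labels[fg] == truth$labels[fg])
    }
  }
  dice_tab <- do.call(rbind, dice_rows)
  med <- vapply(class_names, function(cn)
    stats::median(dice_tab$dice[dice_tab$class == cn], na.rm = TRUE),
    numeric(1))
  structure(list(variant = variant$variant, dice = dice_tab,
                 per_class_median = med,
                 class_average = mean(med, na.rm = TRUE),
                 quadratic = data.frame(image = ids, score = quad,
                                        fold = fold),
                 median_quadratic = stats::median(quad),
                 confusion = conf, fold = fold,
                 accuracy = data.frame(image = ids, fold = fold,
                                       model = acc, prior_atlas = base_acc)),
            class = "autocontext_cv")
}

#' @export
print.autocontext_cv <- function(x, ...) {
  cat("cross-validated auto-context evaluation (", toupper(x$variant),
      "), ", max(x$fold), " folds\n", sep = "")
  cat("\nmedian Dice per class:\n")
  print(round(x$per_class_median, 3))
  cat("class average:", round(x$class_average, 3), "\n")
  cat("median per-image quadratic score:", round(x$median_quadratic, 3), "\n")
  cat("mean pixel accuracy:", round(mean(x$accuracy$model), 3),
      "(prior-atlas baseline:", round(mean(x$accuracy$prior_atlas), 3),
      ")\n")
  invisible(x)
}
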