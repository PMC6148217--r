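#' Configure an auto-context variant
#'
#' Four variants share one training loop: plain auto-context (`"ac"`),
#' auto-context with integral context features (`"ac+ic"`), weighted-atlas
#' auto-context (`"waac"`), and both extensions combined (`"waac+ic"`).
#'
#' @param variant one of `"ac"`, `"ac+ic"`, `"waac"`, `"waac+ic"`.
#' @param T number of iterations, i.e. classifiers in the sequence
#'   (default 5; performance tends to saturate by then).
#' @param m_w number of annotations combined into each weighted atlas
#'   (default 32).
#' @param per_class stratified sample size per class for classifier training
#'   (default 1600, i.e. 8000 locations for K = 5).
#' @param stencil context stencil, a [star_stencil()].
#' @param seed master seed; every random stage derives from it via
#'   [sub_seed()].
#' @param hidden,decay,maxit,tol classifier settings, see [mlp_fit()].
#' @param plain_first_iteration run iteration 1 of the WAAC variants as
#'   plain AC (default TRUE): before any classifier has run, the weighted
#'   atlas would merely duplicate the prior-atlas context features.
#' @return an object of class `"variant_config"`.
#' @export
variant_config <- function(variant = c("ac", "ac+ic", "waac", "waac+ic"),
                           T = 5, m_w = 32, per_class = 1600,
                           stencil = star_stencil(), seed = 1L,
                           hidden = 20, decay = 1e-3, maxit = 500,
                           tol = 1e-5, plain_first_iteration = TRUE) {
  variant <- match.arg(variant)
  stopifnot(T >= 1, m_w >= 1, per_class >= 1)
  structure(list(variant = variant,
                 use_integral = variant %in% c("ac+ic", "waac+ic"),
                 use_weighted_atlas = variant %in% c("waac", "waac+ic"),
                 T = as.integer(T), m_w = as.integer(m_w),
                 per_class = as.integer(per_class), stencil = stencil,
                 seed = as.integer(seed), hidden = as.integer(hidden),
                 decay = decay, maxit = as.integer(maxit), tol = tol,
                 plain_first_iteration = isTRUE(plain_first_iteration)),
            class = "variant_config")
}

#' Stratified sampling of training locations
#'
#' Draws a class-balanced training set: `per_class` foreground cells per
#' class, pooled across all label maps, sampled uniformly without
#' replacement (with replacement only if a class has fewer cells than
#' requested). Deterministic given `seed`.
#'
#' @param maps list of [label_map]s.
#' @param per_class locations per class.
#' @param seed integer seed.
#' @param allow_missing skip absent classes with a warning instead of
#'   erroring (used by the cross-validation harness to retain degenerate
#'   folds).
#' @return data.frame with columns `map` (index into `maps`), `row`, `col`,
#'   `label`, ordered by class.
#' @export
sample_training_locations <- function(maps, per_class, seed = 1L,
                                      allow_missing = FALSE) {
  K <- n_classes(maps[[1]])
  cells <- do.call(rbind, lapply(seq_along(maps), function(j) {
    idx <- which(maps[[j]]$foreground, arr.ind = TRUE)
    cbind(map = j, row = idx[, 1], col = idx[, 2],
          label = maps[[j]]$labels[idx])
  }))
  with_seed(seed, {
    picked <- lapply(seq_len(K), function(k) {
      pool <- which(cells[, "label"] == k)
      if (!length(pool)) {
        msg <- paste0("stratification: class ", k, " (",
                      maps[[1]]$class_names[k],
                      ") is absent from the training pool")
        if (allow_missing) {
          warning(msg, call. = FALSE)
          return(integer(0))
        }
        stop(msg, call. = FALSE)
      }
      pool[sample.int(length(pool), per_class,
                      replace = length(pool) < per_class)]
    })
    as.data.frame(cells[unlist(picked), , drop = FALSE])
  })
}

# Rows of a feature grid at the given (row, col) locations.
grid_rows <- function(fgrid, locations) {
  d <- dim(fgrid)
  n <- nrow(locations)
  base <- (locations[, 2] - 1) * d[1] + locations[, 1]
  fv <- as.vector(fgrid)
  out <- matrix(NA_real_, n, d[3])
  for (f in seq_len(d[3])) out[, f] <- fv[(f - 1) * d[1] * d[2] + base]
  out
}

# Feature block lengths for a variant on a K-class problem.
feature_layout <- function(variant, n_local, K) {
  lay <- c(local = n_local, stencil = nrow(variant$stencil) * K)
  if (variant$use_integral) lay <- c(lay, integral = 2 * K)
  if (variant$use_weighted_atlas)
    lay <- c(lay, atlas = nrow(variant$stencil) * K)
  lay
}

# Assemble the feature matrix for a batch of locations on one image.
# Blocks in fixed order: local, stencil context on the probability map,
# integral context, stencil context on the weighted atlas.
assemble_feature_matrix <- function(local_rows, probs, atlas, locations,
                                    variant, use_atlas) {
  blocks <- list(local = local_rows,
                 stencil = stencil_context_matrix(probs, locations,
                                                  variant$stencil))
  if (variant$use_integral)
    blocks$integral <- integral_context_matrix(probs, locations)
  if (use_atlas) {
    if (is.null(atlas))
      stop("variant ", variant$variant,
           " requires a weighted atlas but none was supplied")
    blocks$atlas <- stencil_context_matrix(atlas, locations, variant$stencil)
  }
  for (b in names(blocks))
    if (!all(is.finite(blocks[[b]])))
      stop("non-finite values in feature block '", b, "'")
  do.call(cbind, blocks)
}

#' Assemble the feature vector for one location
#'
#' Concatenates, in fixed order: the local appearance features, the stencil
#' context on the probability map, then (variant permitting) the integral
#' context and the stencil context on the weighted atlas.
#'
#' @param local a `feature_grid` of local appearance features.
#' @param probs the current [prob_map] of the image.
#' @param atlas optional weighted [atlas][weighted_atlas] (required by WAAC
#'   variants past the first iteration).
#' @param location `(row, col)` foreground cell.
#' @param variant a [variant_config()].
#' @return numeric feature vector.
#' @export
assemble_features <- function(local, probs, atlas = NULL, location,
                              variant = variant_config()) {
  loc <- matrix(as.integer(location), 1, 2)
  if (!probs$foreground[loc[1, 1], loc[1, 2]])
    stop("location is not a foreground cell")
  drop(assemble_feature_matrix(grid_rows(local, loc), probs, atlas, loc,
                               variant, variant$use_weighted_atlas))
}

#' Fit an auto-context segmentation model
#'
#' Trains the sequence of T per-iteration classifiers. Probability maps are
#' initialised from the prior atlas (the unweighted mean of the training
#' annotations); at each iteration a classifier is trained on local
#' appearance features concatenated with context features read from the
#' previous iteration's probability maps (and, for WAAC variants from
#' iteration 2 onward, from per-image weighted atlases computed with
#' self-exclusion), after which every training image is re-classified in
#' full to produce the next round of probability maps.
#'
#' @param x training images: a `pluck_dataset` from [generate_dataset()], a
#'   list of `pluck_sample`s, or a list of `H x W x 3` arrays /
#'   `feature_grid`s (then `labels` is required).
#' @param labels list of [label_map]s or integer matrices at the working
#'   grid resolution (ignored when `x` carries its own annotations).
#' @param variant a [variant_config()].
#' @param features a [decomposition_config()] controlling appearance
#'   features. When `x` is a pluck dataset the default keeps the images'
#'   own resolution (`subsample_factor = 1`).
#' @param allow_missing tolerate classes absent from the training pool
#'   (warning instead of error); see [sample_training_locations()].
#' @return an object of class `"autocontext"` with components `classifiers`,
#'   `prior` (the prior atlas), `pool` (training label maps, kept for atlas
#'   weighting at prediction time), `layout`, `history` (per-iteration
#'   training pixel accuracy) and the configuration.
#' @seealso [predict.autocontext()], [cross_validate()]
#' @export
autocontext <- function(x, labels = NULL, variant = variant_config(),
                        features = NULL, allow_missing = FALSE) {
  if (inherits(x, "pluck_dataset")) x <- x$samples
  if (length(x) && inherits(x[[1]], "pluck_sample")) {
    labels <- lapply(x, `[[`, "labels")
    x <- lapply(x, `[[`, "image")
    if (is.null(features)) features <- decomposition_config(subsample_factor = 1)
  }
  if (is.null(features)) features <- decomposition_config()
  if (length(x) < 2) stop("need at least 2 training images")
  if (is.null(labels) || length(labels) != length(x))
    stop("one label map per training image is required")
  fgrids <- lapply(x, function(im)
    if (inherits(im, "feature_grid")) im else appearance_features(im, features))
  labmaps <- lapply(seq_along(labels), function(j) {
    lm <- labels[[j]]
    if (!inherits(lm, "label_map")) lm <- label_map(lm)
    if (is.null(lm$id)) lm$id <- sprintf("map%04d", j)
    if (!all(dim(lm$labels) == dim(fgrids[[j]])[1:2]))
      stop("label map ", j, " does not match the feature grid (",
           paste(dim(fgrids[[j]])[1:2], collapse = "x"), ")")
    lm
  })
  fit_autocontext(fgrids, labmaps, variant, features, allow_missing)
}

fit_autocontext <- function(fgrids, labmaps, variant, features,
                            allow_missing = FALSE) {
  m <- length(labmaps)
  K <- n_classes(labmaps[[1]])
  n_local <- dim(fgrids[[1]])[3]
  ids <- map_ids(labmaps)
  prior <- prior_atlas(labmaps)
  P <- lapply(labmaps, function(lm)
    prob_map(prior$probs, lm$foreground, lm$class_names, normalize = TRUE))
  Qj <- NULL
  locs <- sample_training_locations(labmaps, variant$per_class,
                                    sub_seed(variant$seed, "sampling"),
                                    allow_missing = allow_missing)
  rows_of <- split(seq_len(nrow(locs)), locs$map)
  loc_mat <- as.matrix(locs[, c("row", "col")])
  local_X <- matrix(NA_real_, nrow(locs), n_local)
  for (j in names(rows_of)) {
    r <- rows_of[[j]]
    local_X[r, ] <- grid_rows(fgrids[[as.integer(j)]],
                              loc_mat[r, , drop = FALSE])
  }
  layout <- feature_layout(variant, n_local, K)
  classifiers <- vector("list", variant$T)
  atlas_from <- if (variant$plain_first_iteration) 2L else 1L
  history <- data.frame(iteration = integer(0), train_accuracy = numeric(0))
  for (t in seq_len(variant$T)) {
    use_atlas_t <- variant$use_weighted_atlas && t >= atlas_from
    if (use_atlas_t && is.null(Qj)) Qj <- rep(list(prior), m)
    nfeat <- if (use_atlas_t || !variant$use_weighted_atlas) sum(layout)
             else sum(layout) - layout[["atlas"]]
    X <- matrix(NA_real_, nrow(locs), nfeat)
    for (j in names(rows_of)) {
      ji <- as.integer(j); r <- rows_of[[j]]
      X[r, ] <- assemble_feature_matrix(local_X[r, , drop = FALSE], P[[ji]],
                                        if (use_atlas_t) Qj[[ji]],
                                        loc_mat[r, , drop = FALSE],
                                        variant, use_atlas_t)
    }
    clf <- mlp_fit(X, locs$label, K, hidden = variant$hidden,
                   decay = variant$decay, maxit = variant$maxit,
                   tol = variant$tol,
                   seed = sub_seed(variant$seed, "classifier", t))
    classifiers[[t]] <- clf
    acc <- numeric(m)
    for (ji in seq_len(m)) {
      all_locs <- which(labmaps[[ji]]$foreground, arr.ind = TRUE)
      Xa <- assemble_feature_matrix(grid_rows(fgrids[[ji]], all_locs),
                                    P[[ji]], if (use_atlas_t) Qj[[ji]],
                                    all_locs, variant, use_atlas_t)
      pr <- predict(clf, Xa)
      P[[ji]] <- probs_at_cells(pr, all_locs, dim(labmaps[[ji]]$labels), K,
                                labmaps[[ji]]$foreground,
                                labmaps[[ji]]$class_names)
      acc[ji] <- mean(max.col(pr, ties.method = "first") ==
                        labmaps[[ji]]$labels[all_locs])
    }
    history <- rbind(history, data.frame(iteration = t,
                                         train_accuracy = mean(acc)))
    if (variant$use_weighted_atlas)
      Qj <- lapply(seq_len(m), function(ji)
        weighted_atlas(labmaps, P[[ji]], variant$m_w, exclude = ids[ji]))
  }
  structure(list(classifiers = classifiers, variant = variant,
                 features = features, layout = layout, prior = prior,
                 pool = labmaps, class_names = labmaps[[1]]$class_names,
                 grid = dim(labmaps[[1]]$labels), history = history),
            class = "autocontext")
}

# Scatter an n x K prediction matrix back onto the grid as a prob_map.
probs_at_cells <- function(pr, cells, d, K, foreground, class_names) {
  probs <- array(1 / K, c(d, K))
  base <- (cells[, 2] - 1) * d[1] + cells[, 1]
  for (k in seq_len(K)) probs[(k - 1) * d[1] * d[2] + base] <- pr[, k]
  prob_map(probs, foreground, class_names, normalize = TRUE)
}

#' Predict with an auto-context model
#'
#' Applies the trained classifier sequence to a new image. The probability
#' map is initialised from the training prior atlas (resampled to the test
#' grid by nearest neighbour if needed); each iteration classifies every
#' foreground cell with the same feature assembly used in training. WAAC
#' variants recompute the weighted atlas from the current probability map
#' after every iteration, using the training pool as candidates (no
#' exclusion at test time).
#'
#' @param object an [autocontext] model.
#' @param image `H x W x 3` array, `feature_grid`, or `pluck_sample`.
#' @param mask logical foreground matrix at grid resolution (taken from the
#'   sample when `image` is a `pluck_sample`; defaults to all cells).
#' @param candidates label maps for atlas weighting (default: the model's
#'   training pool).
#' @param type `"prob"` for the final probability map, `"label"` for its
#'   arg-max labelling.
#' @param all_iterations return an `"autocontext_prediction"` object holding
#'   every iteration's probability map and weighted atlas.
#' @param ... unused.
#' @return a [prob_map], [label_map], or `"autocontext_prediction"` list
#'   with fields `prior`, `iterations`, `atlases`, `final`.
#' @export
predict.autocontext <- function(object, image, mask = NULL,
                                candidates = NULL,
                                type = c("prob", "label"),
                                all_iterations = FALSE, ...) {
  type <- match.arg(type)
  variant <- object$variant
  if (inherits(image, "pluck_sample")) {
    if (is.null(mask)) mask <- image$mask
    image <- image$image
  }
  fgrid <- if (inherits(image, "feature_grid")) image else
    appearance_features(image, object$features)
  d <- dim(fgrid)[1:2]
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!all(dim(mask) == d)) stop("mask does not match the feature grid")
  K <- length(object$class_names)
  prior <- if (all(dim(object$prior$probs)[1:2] == d))
    prob_map(object$prior$probs, mask, object$class_names, normalize = TRUE)
  else resample_prob_map(object$prior, d, mask)
  if (variant$use_weighted_atlas) {
    if (is.null(candidates)) candidates <- object$pool
    if (!all(grid_dim(candidates[[1]]) == d))
      stop("atlas candidates are not on the test grid (",
           paste(d, collapse = "x"), ")")
  }
  cells <- which(mask, arr.ind = TRUE)
  if (!nrow(cells)) stop("degenerate mask: no foreground cells")
  local_rows <- grid_rows(fgrid, cells)
  atlas_from <- if (variant$plain_first_iteration) 2L else 1L
  P <- prior
  Q <- if (variant$use_weighted_atlas && atlas_from == 1L)
    as_atlas(prior, data.frame(id = "prior", weight = 1,
                               similarity = NA_real_))
  maps <- vector("list", variant$T)
  atlases <- if (variant$use_weighted_atlas) vector("list", variant$T)
  for (t in seq_len(variant$T)) {
    use_atlas_t <- variant$use_weighted_atlas && t >= atlas_from
    X <- assemble_feature_matrix(local_rows, P, if (use_atlas_t) Q,
                                 cells, variant, use_atlas_t)
    pr <- predict(object$classifiers[[t]], X)
    P <- probs_at_cells(pr, cells, d, K, mask, object$class_names)
    maps[[t]] <- P
    if (variant$use_weighted_atlas) {
      Q <- weighted_atlas(candidates, P, variant$m_w)
      atlases[[t]] <- Q
    }
  }
  if (all_iterations)
    return(structure(list(prior = prior, iterations = maps,
                          atlases = atlases, final = maps[[variant$T]]),
                     class = "autocontext_prediction"))
  if (type == "label") argmax_labels(maps[[variant$T]]) else maps[[variant$T]]
}

#' @export
print.autocontext <- function(x, ...) {
  v <- x$variant
  cat("auto-context model (", toupper(v$variant), "), T = ", v$T,
      ", K = ", length(x$class_names), "\n", sep = "")
  cat("grid:", paste(x$grid, collapse = " x "),
      "| training images:", length(x$pool), "\n")
  cat("feature blocks:",
      paste(names(x$layout), x$layout, sep = "=", collapse = ", "), "\n")
  cat("final training pixel accuracy:",
      round(utils::tail(x$history$train_accuracy, 1), 4), "\n")
  invisible(x)
}

#' @export
summary.autocontext <- function(object, ...) {
  structure(list(model = object), class = "summary.autocontext")
}

#' @export
print.summary.autocontext <- function(x, ...) {
  print(x$model)
  cat("\nper-iteration training pixel accuracy:\n")
  print(x$model$history, row.names = FALSE)
  prior_mass <- apply(matrix(x$model$prior$probs,
                             prod(x$model$grid),
                             length(x$model$class_names))[
                               as.vector(x$model$prior$foreground), ,
                               drop = FALSE], 2, mean)
  names(prior_mass) <- x$model$class_names
  cat("\nprior atlas mean foreground class mass:\n")
  print(round(prior_mass, 4))
  invisible(x)
}

#' @export
plot.autocontext <- function(x, ...) {
  graphics::plot(x$history$iteration, x$history$train_accuracy, type = "b",
                 xlab = "iteration", ylab = "training pixel accuracy",
                 main = paste("auto-context training,",
                              toupper(x$variant$variant)), ...)
  invisible(x)
}
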