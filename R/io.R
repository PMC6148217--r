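#' Image and map file formats
#'
#' Conventions used on disk: colour images are sRGB PNG (or TIFF); label
#' maps are greyscale PNG whose 8-bit pixel value is the class index (0 =
#' background); masks are binary PNG; probability maps and atlases are
#' multi-page 32-bit float TIFF, one page per class in class order, with a
#' JSON sidecar (`<file>.json`) recording class names and grid shape.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @return `read_image()` returns an `H x W x 3` array in `[0, 1]`.
#' @name pluckseg_io
NULL

#' @rdname pluckseg_io
#' @export
read_image <- function(path) {
  img <- switch(tolower(tools::file_ext(path)),
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", path))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname pluckseg_io
#' @param image `H x W x 3` array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  switch(tolower(tools::file_ext(path)),
         png = png::writePNG(image, path),
         tif = , tiff = tiff::writeTIFF(image, path),
         stop("unsupported image format: ", path))
  invisible(path)
}

#' @rdname pluckseg_io
#' @param K,class_names class metadata for the returned [label_map].
#' @export
read_label_map <- function(path, K = 5, class_names = NULL) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  label_map(round(m * 255), K = K, class_names = class_names)
}

#' @rdname pluckseg_io
#' @param map a [label_map] (or integer matrix).
#' @export
write_label_map <- function(map, path) {
  labels <- if (inherits(map, "label_map")) map$labels else map
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname pluckseg_io
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' @rdname pluckseg_io
#' @param mask logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname pluckseg_io
#' @param pm a [prob_map] (or atlas).
#' @export
write_prob_map <- function(pm, path) {
  d <- dim(pm$probs)
  pages <- lapply(seq_len(d[3]), function(k) pm$probs[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(class_names = pm$class_names,
                            shape = d[1:2]),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pluckseg_io
#' @param foreground optional logical matrix; default: all cells.
#' @export
read_prob_map <- function(path, foreground = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  probs <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  prob_map(probs, foreground, meta$class_names, normalize = TRUE)
}

#' @rdname pluckseg_io
#' @param fgrid a `feature_grid` from [haar_feature_grid()]; written as a
#'   multi-page 32-bit float TIFF (one page per feature) with a JSON
#'   sidecar recording the sub-sampling factor, source shape and feature
#'   names.
#' @export
write_feature_grid <- function(fgrid, path) {
  d <- dim(fgrid)
  # TIFF sample values live in [0, 1]; each page is stored affinely
  # rescaled, with the offset and range recorded in the sidecar
  lo <- apply(fgrid, 3, min)
  rg <- pmax(apply(fgrid, 3, max) - lo, 1e-30)
  pages <- lapply(seq_len(d[3]), function(f) {
    m <- (fgrid[, , f] - lo[f]) / rg[f]
    dim(m) <- d[1:2]
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(subsample_factor = attr(fgrid, "subsample_factor"),
                            source_shape = attr(fgrid, "source_shape"),
                            feature_names = dimnames(fgrid)[[3]],
                            page_offset = lo, page_range = rg),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pluckseg_io
#' @export
read_feature_grid <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- lapply(seq_along(pages), function(f)
    pages[[f]] * meta$page_range[f] + meta$page_offset[f])
  out <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  dimnames(out) <- list(NULL, NULL, meta$feature_names)
  structure(out, subsample_factor = meta$subsample_factor,
            source_shape = meta$source_shape,
            class = c("feature_grid", "array"))
}

#' Write a synthetic pluck dataset to a directory
#'
#' Writes `images/<id>.png`, `labels/<id>.png`, `masks/<id>.png` and
#' `manifest.csv`.
#'
#' @param dataset a `pluck_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pluck_dataset <- function(dataset, dir) {
  for (sub in c("images", "labels", "masks"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (s in dataset$samples) {
    id <- s$labels$id
    write_image(s$image, file.path(dir, "images", paste0(id, ".png")))
    write_label_map(s$labels, file.path(dir, "labels", paste0(id, ".png")))
    write_mask(s$mask, file.path(dir, "masks", paste0(id, ".png")))
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a pluck dataset directory
#'
#' @param dir directory written by [write_pluck_dataset()].
#' @return a `pluck_dataset`.
#' @export
read_pluck_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$id[i]
    labels <- read_label_map(file.path(dir, "labels", paste0(id, ".png")))
    labels$id <- id
    structure(list(image = read_image(file.path(dir, "images",
                                                paste0(id, ".png"))),
                   labels = labels,
                   mask = read_mask(file.path(dir, "masks",
                                              paste0(id, ".png"))),
                   presence = unlist(manifest[i, labels$class_names]),
                   params = NULL),
              class = "pluck_sample")
  })
  structure(list(samples = samples, manifest = manifest, seed = NA),
            class = "pluck_dataset")
}

#' Persist a fitted auto-context model as a directory
#'
#' Writes one JSON file per iteration classifier (weights and input
#' scaling), the prior atlas as multi-page float TIFF, the training pool's
#' label maps as greyscale PNGs, and a `metadata.json` with the variant
#' configuration, stencil offsets, feature layout and class names.
#'
#' @param model an [autocontext] model.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_autocontext <- function(model, dir) {
  dir.create(file.path(dir, "pool"), recursive = TRUE, showWarnings = FALSE)
  v <- model$variant
  meta <- list(variant = v$variant, T = v$T, m_w = v$m_w,
               per_class = v$per_class, seed = v$seed, hidden = v$hidden,
               decay = v$decay, maxit = v$maxit, tol = v$tol,
               plain_first_iteration = v$plain_first_iteration,
               stencil = unclass(v$stencil),
               features = unclass(model$features),
               layout = as.list(model$layout),
               class_names = model$class_names, grid = model$grid,
               history = model$history,
               pool_ids = vapply(model$pool, `[[`, character(1), "id"))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (t in seq_along(model$classifiers)) {
    clf <- model$classifiers[[t]]
    jsonlite::write_json(clf[c("weights", "p", "hidden", "K", "center",
                               "scale", "decay", "loss", "seed")],
                         file.path(dir, sprintf("classifier%02d.json", t)),
                         auto_unbox = TRUE, digits = NA)
  }
  write_prob_map(model$prior, file.path(dir, "prior_atlas.tif"))
  write_mask(model$prior$foreground, file.path(dir, "prior_mask.png"))
  for (lm in model$pool)
    write_label_map(lm, file.path(dir, "pool", paste0(lm$id, ".png")))
  invisible(dir)
}

#' Load a persisted auto-context model
#'
#' @param dir directory written by [write_autocontext()].
#' @return an [autocontext] model.
#' @export
read_autocontext <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  stencil <- structure(matrix(as.integer(meta$stencil), ncol = 2,
                              dimnames = list(NULL, c("row", "col"))),
                       class = c("stencil", "matrix"))
  variant <- variant_config(meta$variant, T = meta$T, m_w = meta$m_w,
                            per_class = meta$per_class, stencil = stencil,
                            seed = meta$seed, hidden = meta$hidden,
                            decay = meta$decay, maxit = meta$maxit,
                            tol = meta$tol,
                            plain_first_iteration = meta$plain_first_iteration)
  classifiers <- lapply(seq_len(meta$T), function(t) {
    clf <- jsonlite::read_json(file.path(dir,
                                         sprintf("classifier%02d.json", t)),
                               simplifyVector = TRUE)
    structure(clf, class = "pluckseg_mlp")
  })
  fg <- read_mask(file.path(dir, "prior_mask.png"))
  prior <- as_atlas(read_prob_map(file.path(dir, "prior_atlas.tif"), fg),
                    data.frame(id = meta$pool_ids,
                               weight = 1 / length(meta$pool_ids),
                               similarity = NA_real_))
  pool <- lapply(meta$pool_ids, function(id) {
    lm <- read_label_map(file.path(dir, "pool", paste0(id, ".png")),
                         K = length(meta$class_names),
                         class_names = meta$class_names)
    lm$id <- id
    lm
  })
  structure(list(classifiers = classifiers, variant = variant,
                 features = do.call(decomposition_config, meta$features),
                 layout = unlist(meta$layout), prior = prior, pool = pool,
                 class_names = meta$class_names, grid = meta$grid,
                 history = as.data.frame(meta$history)),
            class = "autocontext")
}
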