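#' Parameters of the synthetic pluck generator
#'
#' The generator emulates the structure of vertically hung organ groups
#' ("plucks") photographed on an inspection line: a tall foreground blob
#' anchored to a hook at the top row, partitioned top-to-bottom into
#' *upper* (trachea/tongue), a *lungs* band containing a *heart* ellipse,
#' a *diaphragm* band and, almost always, a *liver* section.
#'
#' Orientation around the vertical axis drives two coupled effects observed
#' in real plucks: as the dorsal aspect turns towards the camera
#' (`|orientation| -> 1`) the visible heart area shrinks to zero, and the
#' visible diaphragm band thins while the liver takes up a larger share of
#' the object. The liver is omitted entirely with a small probability.
#' Class colours are drawn with per-cell Gaussian texture noise around hue
#' centres chosen so that the heart and the liver are nearly
#' indistinguishable by colour alone -- separating them requires spatial
#' context, which is precisely what the context features provide.
#'
#' @param grid `(h, w)` grid size in cells (default `c(180, 60)`, the
#'   working resolution of the pipeline; minimum `c(40, 20)`).
#' @param orientation number in `[-1, 1]`; 0 faces the heart to the camera,
#'   +/-1 hides it completely.
#' @param liver_missing probability that the liver is absent (default 0.02).
#' @param noise_sd standard deviation of the per-channel colour texture
#'   noise (default 0.05, on the `[0, 1]` colour scale).
#' @param specular_rate rate of near-white specular speckles (default 0.005).
#' @param contamination expected number of dark surface-contamination
#'   patches per image (default 1.5). Patches share the heart/liver hue but
#'   keep the underlying organ's label, so local appearance alone cannot
#'   be trusted around them.
#' @param colour_shift optional `K x 3` matrix added to the class colour
#'   means (used for per-sample jitter by [generate_dataset()]).
#' @param seed integer seed; the sample is fully determined by it.
#' @return an object of class `"pluck_params"`.
#' @export
pluck_params <- function(grid = c(180, 60), orientation = 0,
                         liver_missing = 0.02, noise_sd = 0.05,
                         specular_rate = 0.005, contamination = 1.5,
                         colour_shift = NULL, seed = 1L) {
  stopifnot(length(grid) == 2, grid[1] >= 40, grid[2] >= 20,
            abs(orientation) <= 1, liver_missing >= 0, liver_missing <= 1,
            noise_sd >= 0, specular_rate >= 0, specular_rate <= 1,
            contamination >= 0)
  structure(list(grid = as.integer(grid), orientation = orientation,
                 liver_missing = liver_missing, noise_sd = noise_sd,
                 specular_rate = specular_rate, contamination = contamination,
                 colour_shift = colour_shift,
                 seed = as.integer(seed)),
            class = "pluck_params")
}

pluck_colours <- function() {
  rbind(background = c(0.10, 0.11, 0.14),
        upper      = c(0.82, 0.68, 0.52),
        heart      = c(0.52, 0.14, 0.16),
        lungs      = c(0.90, 0.52, 0.56),
        diaphragm  = c(0.58, 0.46, 0.40),
        liver      = c(0.50, 0.16, 0.15))
}

#' Generate one synthetic pluck sample
#'
#' @param params a [pluck_params()].
#' @return an object of class `"pluck_sample"`: list with `image`
#'   (`h x w x 3` in `[0, 1]`), `labels` (a [label_map] with classes upper,
#'   heart, lungs, diaphragm, liver), `mask`, `presence` (named logical),
#'   and `params`.
#' @export
#' @examples
#' s <- generate_pluck(pluck_params(grid = c(60, 30), seed = 7))
#' s$presence
generate_pluck <- function(params = pluck_params()) {
  with_seed(params$seed, generate_pluck_impl(params))
}

generate_pluck_impl <- function(params) {
  h <- params$grid[1]; w <- params$grid[2]
  orient <- params$orientation
  vis <- 1 - abs(orient) # heart visibility factor
  bottom <- round(h * stats::runif(1, 0.92, 0.97))
  r_upper <- round(h * stats::runif(1, 0.12, 0.16))
  r_lungs <- round(h * stats::runif(1, 0.46, 0.54))
  # dorsal aspect (vis -> 0) thins the visible diaphragm band
  th_diaph <- max(2, round(h * (0.03 + 0.09 * vis) * stats::runif(1, 0.85, 1.15)))
  r_diaph <- min(r_lungs + th_diaph, bottom - max(4, round(0.05 * h)))
  liver_present <- stats::runif(1) >= params$liver_missing
  if (!liver_present) bottom <- r_diaph
  # smooth half-width profile, narrow at the hook, bulging mid-object
  rr <- seq_len(bottom) / bottom
  base_hw <- w * (0.10 + 0.34 * sin(pi * rr^0.8))
  wig <- stats::filter(stats::rnorm(bottom, 0, 0.05 * w), rep(1 / 9, 9),
                       circular = TRUE)
  hw <- pmax(1.5, pmin(0.47 * w, base_hw + as.numeric(wig)))
  centre <- w / 2 + stats::runif(1, -0.03, 0.03) * w
  labels <- matrix(0L, h, w)
  cols <- matrix(seq_len(w), bottom, w, byrow = TRUE)
  inside <- abs(cols - centre) <= hw
  band <- ifelse(seq_len(bottom) <= r_upper, 1L,
                 ifelse(seq_len(bottom) <= r_lungs, 3L,
                        ifelse(seq_len(bottom) <= r_diaph, 4L, 5L)))
  labels[seq_len(bottom), ] <- ifelse(inside, band[row(cols)], 0L)
  # heart: an ellipse in the upper half of the lungs band whose visible
  # width collapses with orientation; the side it emerges on as the pluck
  # rotates is arbitrary (the hook constrains height, not rotation sense)
  if (vis > 0) {
    hr <- (r_upper + r_lungs) / 2 - 0.1 * (r_lungs - r_upper)
    side <- sample(c(-1, 1), 1)
    hc <- centre + side * abs(orient) * 0.25 * w
    a <- 0.38 * (r_lungs - r_upper) / 2 + 0.22 * (r_lungs - r_upper) / 2
    b <- vis * 0.42 * mean(hw[max(1, round(hr) + (-2:2))])
    if (b >= 0.5) {
      er <- matrix(seq_len(h), h, w)
      ec <- matrix(seq_len(w), h, w, byrow = TRUE)
      ell <- ((er - hr) / a)^2 + ((ec - hc) / b)^2 <= 1
      labels[ell & labels == 3L] <- 2L
    }
  }
  mask <- labels > 0L
  presence <- c(upper = TRUE, heart = any(labels == 2L), lungs = TRUE,
                diaphragm = TRUE, liver = liver_present)
  colours <- pluck_colours()
  if (!is.null(params$colour_shift))
    colours[-1, ] <- colours[-1, ] + params$colour_shift
  base_col <- colours[labels + 1L, ]
  dim(base_col) <- c(h, w, 3)
  # dark surface contamination (blood draining from the trachea): heart-like
  # hue painted over whatever organ it sits on; labels are unaffected.
  # Patches concentrate on the lungs band, where a dark heart-coloured blob
  # is locally indistinguishable from the heart itself.
  n_pat <- stats::rpois(1, params$contamination)
  if (n_pat > 0 && any(mask)) {
    fg_cells <- which(mask, arr.ind = TRUE)
    lungs_cells <- fg_cells[fg_cells[, 1] > r_upper &
                              fg_cells[, 1] <= r_lungs, , drop = FALSE]
    er <- matrix(seq_len(h), h, w); ec <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(n_pat)) {
      pool <- if (nrow(lungs_cells) && stats::runif(1) < 0.6) lungs_cells
              else fg_cells
      ctr <- pool[sample.int(nrow(pool), 1), ]
      ra <- stats::runif(1, 0.03, 0.08) * h
      rb <- stats::runif(1, 0.06, 0.16) * w
      patch <- mask & (((er - ctr[1]) / ra)^2 + ((ec - ctr[2]) / rb)^2 <= 1)
      tint <- colours["heart", ] + stats::rnorm(3, 0, 0.03)
      for (ch in 1:3) {
        plane <- base_col[, , ch]
        plane[patch] <- tint[ch]
        base_col[, , ch] <- plane
      }
    }
  }
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    img[, , ch] <- base_col[, , ch] + stats::rnorm(h * w, 0, params$noise_sd)
  }
  if (params$specular_rate > 0) {
    spec <- mask & matrix(stats::runif(h * w) < params$specular_rate, h, w)
    if (any(spec)) {
      glint <- 0.92 + stats::runif(sum(spec), 0, 0.06)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[spec] <- glint
        img[, , ch] <- plane
      }
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  structure(list(image = img,
                 labels = label_map(labels, K = 5,
                                    class_names = rownames(colours)[-1]),
                 mask = mask, presence = presence, params = params),
            class = "pluck_sample")
}

#' @export
print.pluck_sample <- function(x, ...) {
  cat("synthetic pluck sample, grid ",
      paste(dim(x$labels$labels), collapse = " x "),
      ", orientation ", round(x$params$orientation, 3), "\n", sep = "")
  cat("present:", paste(names(x$presence)[x$presence], collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic pluck dataset
#'
#' Draws per-sample parameters -- orientation uniform on `[-1, 1]`, liver
#' presence Bernoulli, small per-sample class colour jitter -- and
#' generates `n` samples, optionally writing them to disk as PNG images
#' (sRGB), greyscale label PNGs (pixel value = class index), binary mask
#' PNGs and a `manifest.csv` of presence records.
#'
#' @param n number of samples.
#' @param seed master seed.
#' @param grid grid size passed to [pluck_params()].
#' @param liver_missing,noise_sd,specular_rate see [pluck_params()].
#' @param colour_jitter sd of the per-sample shift of class colour means.
#' @param dir optional output directory.
#' @return an object of class `"pluck_dataset"`: list with `samples` and a
#'   `manifest` data.frame (id, orientation, per-class presence).
#' @export
generate_dataset <- function(n, seed = 1L, grid = c(180, 60),
                             liver_missing = 0.02, noise_sd = 0.05,
                             specular_rate = 0.005, contamination = 1.5,
                             colour_jitter = 0.02, dir = NULL) {
  stopifnot(n >= 1)
  draws <- with_seed(sub_seed(seed, "dataset"), list(
    orientation = stats::runif(n, -1, 1),
    shift = array(stats::rnorm(n * 5 * 3, 0, colour_jitter), c(n, 5, 3))))
  samples <- lapply(seq_len(n), function(i) {
    s <- generate_pluck(pluck_params(
      grid = grid, orientation = draws$orientation[i],
      liver_missing = liver_missing, noise_sd = noise_sd,
      specular_rate = specular_rate, contamination = contamination,
      colour_shift = draws$shift[i, , ],
      seed = sub_seed(seed, "sample", i)))
    s$labels$id <- sprintf("pluck%04d", i)
    s
  })
  manifest <- data.frame(
    id = vapply(samples, function(s) s$labels$id, character(1)),
    orientation = draws$orientation,
    t(vapply(samples, function(s) s$presence, logical(5))))
  ds <- structure(list(samples = samples, manifest = manifest, seed = seed),
                  class = "pluck_dataset")
  if (!is.null(dir)) write_pluck_dataset(ds, dir)
  ds
}

#' @export
print.pluck_dataset <- function(x, ...) {
  cat("synthetic pluck dataset:", nrow(x$manifest), "samples, grid",
      paste(dim(x$samples[[1]]$labels$labels), collapse = " x "), "\n")
  cat("heart visible in", sum(x$manifest$heart), "| liver present in",
      sum(x$manifest$liver), "\n")
  invisible(x)
}
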