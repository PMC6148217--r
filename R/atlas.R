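#' One-hot encoding of a label map
#'
#' Turns a label map into a probability map that puts probability one on the
#' annotated class of each foreground cell. Background cells receive the
#' uniform padding distribution. One-hot maps are the summands of both the
#' prior atlas and the weighted atlas.
#'
#' @param map a [label_map].
#' @return a [prob_map] on the same grid.
#' @export
one_hot <- function(map) {
  stopifnot(inherits(map, "label_map"))
  d <- dim(map$labels)
  K <- n_classes(map)
  probs <- array(0, c(d, K))
  lab <- as.vector(map$labels)
  fg <- lab > 0
  idx <- which(fg) + (lab[fg] - 1) * d[1] * d[2]
  probs[idx] <- 1
  prob_map(probs, map$foreground, map$class_names)
}

#' Prior atlas: the unweighted average of training label maps
#'
#' Averages the one-hot encodings of a set of annotated label maps cell by
#' cell, giving a spatial prior over class labels used to initialise the
#' auto-context iteration. The atlas foreground is the union of the
#' contributing foregrounds.
#'
#' @param maps list of [label_map]s on a common grid with common K.
#' @return an object of class `c("atlas", "prob_map")`; the `provenance`
#'   field records contributing identifiers and weights (here all `1/m`).
#' @export
#' @examples
#' a <- matrix(c(1, 1, 2, 2), 2)
#' b <- matrix(c(1, 1, 2, 3), 2)
#' atl <- prior_atlas(list(label_map(a, K = 3), label_map(b, K = 3)))
#' atl$probs[2, 2, ]   # (0, .5, .5)
prior_atlas <- function(maps) {
  stopifnot(length(maps) >= 1)
  for (m in maps) check_same_grid(maps[[1]], m)
  ids <- map_ids(maps)
  acc <- one_hot(maps[[1]])$probs
  fg <- maps[[1]]$foreground
  for (m in maps[-1]) {
    acc <- acc + one_hot(m)$probs
    fg <- fg | m$foreground
  }
  as_atlas(prob_map(acc / length(maps), fg, maps[[1]]$class_names,
                    normalize = TRUE),
           data.frame(id = ids, weight = 1 / length(maps),
                      similarity = NA_real_))
}

as_atlas <- function(pm, provenance) {
  pm$provenance <- provenance
  class(pm) <- c("atlas", "prob_map")
  pm
}

map_ids <- function(maps) {
  ids <- vapply(seq_along(maps), function(j) {
    id <- maps[[j]]$id
    if (is.null(id)) sprintf("map%04d", j) else as.character(id)
  }, character(1))
  if (anyDuplicated(ids)) stop("label map identifiers must be unique")
  ids
}

#' Mean class F1-score between an annotation and a probability map
#'
#' The similarity that drives atlas weighting. The probability map is first
#' hard-assigned by per-cell arg-max over its foreground; for every class the
#' F1-score (harmonic mean of precision and recall, `2pr/(p+r)`) of the
#' predicted region against the reference region is computed, and the scores
#' are averaged. Classes absent from both maps are excluded from the mean
#' (their F1 is undefined); a class present on exactly one side scores 0, so
#' hallucinating a missing part or missing a present part is penalised.
#'
#' @param reference a [label_map].
#' @param predicted a [prob_map] on the same grid.
#' @return a number in `[0, 1]`.
#' @export
f1_similarity <- function(reference, predicted) {
  stopifnot(inherits(reference, "label_map"), inherits(predicted, "prob_map"))
  check_same_grid(reference, predicted)
  f1_from_labels(reference$labels, argmax_labels(predicted)$labels,
                 n_classes(reference))
}

# F1 core on hard labels; hot path of weighted_atlas, so the predicted
# arg-max is computed once by the caller.
f1_from_labels <- function(ref, pred, K) {
  nref <- tabulate(ref[ref > 0L], nbins = K)
  npred <- tabulate(pred[pred > 0L], nbins = K)
  both <- ref == pred & ref > 0L
  tp <- tabulate(ref[both], nbins = K)
  keep <- nref > 0 | npred > 0
  if (!any(keep)) return(0)
  f1 <- ifelse(tp > 0, 2 * tp / (nref + npred), 0)
  mean(f1[keep])
}

#' Similarity-weighted adaptive atlas
#'
#' Builds an atlas tailored to one image: every candidate annotation is
#' scored by [f1_similarity()] against the image's current probability map,
#' the `m_w` best-matching annotations are selected, and their one-hot maps
#' are combined with weights proportional to their similarities. During
#' training the image's own annotation is excluded via `exclude`; at test
#' time no exclusion applies. Ties at the selection boundary are broken by
#' candidate identifier (ascending) for determinism; if every selected
#' weight is zero the selected maps are averaged unweighted.
#'
#' @param candidates list of [label_map]s (the training pool).
#' @param predicted the image's current [prob_map].
#' @param m_w number of annotations to select (default 32).
#' @param exclude optional identifier to drop from the pool.
#' @return an object of class `c("atlas", "prob_map")` whose `provenance`
#'   lists the selected identifiers, normalised weights and raw similarities.
#' @export
weighted_atlas <- function(candidates, predicted, m_w = 32, exclude = NULL) {
  stopifnot(length(candidates) >= 1, m_w >= 1)
  ids <- map_ids(candidates)
  if (!is.null(exclude)) {
    keep <- ids != as.character(exclude)
    candidates <- candidates[keep]
    ids <- ids[keep]
  }
  if (!length(candidates))
    stop("empty candidate pool after exclusion")
  for (m in candidates) check_same_grid(m, predicted)
  pred_lab <- argmax_labels(predicted)$labels
  K <- n_classes(predicted)
  w <- vapply(candidates, function(m)
    f1_from_labels(m$labels, pred_lab, K), numeric(1))
  ord <- order(-w, ids)
  sel <- ord[seq_len(min(m_w, length(ord)))]
  ws <- w[sel]
  norm <- if (sum(ws) > 0) ws / sum(ws) else rep(1 / length(sel), length(sel))
  acc <- one_hot(candidates[[sel[1]]])$probs * norm[1]
  fg <- candidates[[sel[1]]]$foreground
  for (i in seq_along(sel)[-1]) {
    acc <- acc + one_hot(candidates[[sel[i]]])$probs * norm[i]
    fg <- fg | candidates[[sel[i]]]$foreground
  }
  as_atlas(prob_map(acc, fg, candidates[[1]]$class_names, normalize = TRUE),
           data.frame(id = ids[sel], weight = norm, similarity = ws))
}
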