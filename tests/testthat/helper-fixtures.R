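# Small random fixtures and brute-force oracles shared across test files.

random_label_map <- function(h, w, K, seed, p_fg = 0.8, id = NULL) {
  pluckseg::sub_seed(seed, "lm") # touch to keep seeds distinct per use-site
  set.seed(seed)
  labels <- matrix(ifelse(runif(h * w) < p_fg,
                          sample.int(K, h * w, replace = TRUE), 0L), h, w)
  pluckseg::label_map(labels, K = K, id = id)
}

random_prob_map <- function(h, w, K, seed, p_fg = 0.8) {
  set.seed(seed)
  probs <- array(rgamma(h * w * K, 1), c(h, w, K))
  probs <- probs / array(rep(apply(probs, c(1, 2), sum), K), c(h, w, K))
  fg <- matrix(runif(h * w) < p_fg, h, w)
  pluckseg::prob_map(probs, fg, normalize = TRUE)
}

# Brute-force oracle: stencil context by explicit per-point loop.
oracle_stencil_context <- function(pm, loc, stencil) {
  d <- dim(pm$probs); K <- d[3]
  out <- numeric(0)
  for (s in seq_len(nrow(stencil))) {
    r <- loc[1] + stencil[s, 1]; c <- loc[2] + stencil[s, 2]
    if (r >= 1 && r <= d[1] && c >= 1 && c <= d[2] && pm$foreground[r, c])
      out <- c(out, pm$probs[r, c, ])
    else out <- c(out, rep(1 / K, K))
  }
  out
}

# Brute-force oracle: integral context by explicit double loop.
oracle_integral_context <- function(pm, loc) {
  d <- dim(pm$probs); K <- d[3]
  row_acc <- numeric(K); row_n <- 0
  img_acc <- numeric(K); img_n <- 0
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    if (!pm$foreground[r, c]) next
    img_acc <- img_acc + pm$probs[r, c, ]; img_n <- img_n + 1
    if (r == loc[1]) { row_acc <- row_acc + pm$probs[r, c, ]; row_n <- row_n + 1 }
  }
  c(row_acc / row_n, img_acc / img_n)
}

# Brute-force oracle: per-cell average of one-hot maps.
oracle_prior_atlas <- function(maps) {
  d <- dim(maps[[1]]$labels); K <- pluckseg:::n_classes(maps[[1]])
  probs <- array(0, c(d, K))
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    acc <- numeric(K)
    for (m in maps) {
      l <- m$labels[r, c]
      acc <- acc + if (l > 0) replace(numeric(K), l, 1) else rep(1 / K, K)
    }
    probs[r, c, ] <- acc / length(maps)
  }
  probs
}

# Brute-force oracle: rank similarities, select, renormalise, weighted sum.
oracle_weighted_atlas <- function(candidates, predicted, m_w, exclude = NULL) {
  ids <- vapply(seq_along(candidates), function(j) {
    id <- candidates[[j]]$id
    if (is.null(id)) sprintf("map%04d", j) else id
  }, character(1))
  keep <- if (is.null(exclude)) rep(TRUE, length(ids)) else ids != exclude
  candidates <- candidates[keep]; ids <- ids[keep]
  w <- sapply(candidates, pluckseg::f1_similarity, predicted = predicted)
  sel <- order(-w, ids)[seq_len(min(m_w, length(w)))]
  ws <- w[sel]
  ws <- if (sum(ws) > 0) ws / sum(ws) else rep(1 / length(sel), length(sel))
  d <- dim(candidates[[1]]$labels); K <- pluckseg:::n_classes(candidates[[1]])
  probs <- array(0, c(d, K))
  for (i in seq_along(sel))
    probs <- probs + ws[i] * pluckseg::one_hot(candidates[[sel[i]]])$probs
  probs
}

# Brute-force oracle: per-class Dice by explicit cell counting.
oracle_dice <- function(reference, predicted) {
  K <- pluckseg:::n_classes(reference)
  d <- dim(reference$labels)
  out <- numeric(K)
  for (k in seq_len(K)) {
    nref <- npred <- nboth <- 0
    for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
      a <- reference$labels[r, c] == k
      b <- predicted$labels[r, c] == k
      nref <- nref + a; npred <- npred + b; nboth <- nboth + (a && b)
    }
    out[k] <- if (nref == 0) NA_real_ else 2 * nboth / (nref + npred)
  }
  out
}

# Brute-force oracle: mean quadratic score by explicit double loop.
oracle_quadratic <- function(pm, reference) {
  d <- dim(reference$labels)
  tot <- 0; n <- 0
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    y <- reference$labels[r, c]
    if (y == 0) next
    p <- pm$probs[r, c, ]
    tot <- tot + 2 * p[y] - sum(p^2)
    n <- n + 1
  }
  tot / n
}

# Brute-force oracle: confusion matrix by explicit double loop.
oracle_confusion <- function(reference, predicted) {
  K <- pluckseg:::n_classes(reference)
  m <- matrix(0L, K, K)
  d <- dim(reference$labels)
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    a <- reference$labels[r, c]; b <- predicted$labels[r, c]
    if (a > 0 && b > 0) m[a, b] <- m[a, b] + 1L
  }
  m
}

foreground_accuracy <- function(truth, labelled) {
  fg <- truth$foreground
  mean(labelled$labels[fg] == truth$labels[fg])
}

with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  force(code)
}

tiny_variant <- function(variant = "ac", seed = 1, T = 2, ...) {
  pluckseg::variant_config(variant, T = T, m_w = 2, per_class = 60,
                           stencil = pluckseg::star_stencil(6, c(2, 5)),
                           maxit = 40, seed = seed, ...)
}
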