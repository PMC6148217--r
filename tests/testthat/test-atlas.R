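test_that("one-hot encoding puts unit mass on the label and padding elsewhere", {
  lm <- label_map(matrix(c(3L, 0L), 1, 2), K = 5)
  oh <- one_hot(lm)
  expect_equal(oh$probs[1, 1, ], c(0, 0, 1, 0, 0))
  expect_equal(oh$probs[1, 2, ], rep(0.2, 5))
  all_bg <- one_hot(label_map(matrix(0L, 3, 3), K = 4))
  expect_true(all(all_bg$probs == 0.25))
  expect_error(label_map(matrix(7L, 1, 1), K = 5), "0..K")
  # round trip: argmax of one-hot recovers the labels
  for (seed in 1:10) {
    lm <- random_label_map(6, 5, 4, seed)
    expect_equal(argmax_labels(one_hot(lm))$labels, lm$labels)
  }
})

test_that("prior atlas is the cell-wise mean of one-hot maps", {
  lm <- random_label_map(5, 4, 3, seed = 1)
  same <- prior_atlas(list(lm, lm, lm))
  expect_equal(same$probs, one_hot(lm)$probs, tolerance = 1e-12)
  # two maps disagreeing at one cell average to (0.5, 0.5, 0, ...)
  a <- label_map(matrix(1L, 2, 2), K = 3)
  b <- label_map(matrix(c(2L, 1L, 1L, 1L), 2, 2), K = 3)
  atl <- prior_atlas(list(a, b))
  expect_equal(atl$probs[1, 1, ], c(0.5, 0.5, 0))
  expect_equal(atl$probs[2, 2, ], c(1, 0, 0))
  # random pools match the explicit cell-loop oracle
  for (seed in 1:8) {
    maps <- lapply(1:5, function(j) random_label_map(6, 5, 3, seed * 10 + j))
    expect_equal(prior_atlas(maps)$probs, oracle_prior_atlas(maps),
                 tolerance = 1e-12)
  }
  expect_error(prior_atlas(list(a, random_label_map(9, 9, 3, 1))),
               "not compatible")
})

test_that("atlas cells are valid distributions and provenance sums to one", {
  maps <- lapply(1:6, function(j) random_label_map(7, 5, 5, 400 + j))
  atl <- prior_atlas(maps)
  s <- apply(atl$probs, c(1, 2), sum)
  expect_true(all(abs(s - 1) < 1e-6))
  expect_equal(sum(atl$provenance$weight), 1, tolerance = 1e-12)
})

test_that("f1 similarity: perfect match, disjoint maps, hand contingency", {
  lm <- random_label_map(6, 6, 3, seed = 5)
  expect_equal(f1_similarity(lm, one_hot(lm)), 1)
  # arg-max disjoint from the reference for every class
  a <- label_map(matrix(c(1L, 1L, 2L, 2L), 1, 4), K = 2)
  b <- label_map(matrix(c(2L, 2L, 1L, 1L), 1, 4), K = 2)
  expect_equal(f1_similarity(a, one_hot(b)), 0)
  # 4x4 toy with one half-overlapping class, contingency counted by hand:
  # ref class 1 = rows 1:2 (8 cells), pred class 1 = rows 2:3 (8 cells),
  # overlap 4 -> p = r = 1/2, F1_1 = 1/2; class 2 mirrors it.
  ref <- label_map(rbind(matrix(1L, 2, 4), matrix(2L, 2, 4)), K = 2)
  pred <- label_map(rbind(matrix(2L, 1, 4), matrix(1L, 2, 4),
                          matrix(2L, 1, 4)), K = 2)
  expect_equal(f1_similarity(ref, one_hot(pred)), 0.5)
})

test_that("f1 similarity class-absence rules", {
  # class absent from both maps is excluded from the mean
  ref <- label_map(matrix(c(1L, 1L, 2L, 2L), 2, 2), K = 5)
  expect_equal(f1_similarity(ref, one_hot(ref)), 1)
  # class present on one side only contributes F1 = 0
  pred <- label_map(matrix(c(1L, 1L, 2L, 3L), 2, 2), K = 5)
  # class1: p=r=1 -> 1; class2: tp=1, p=1, r=1/2 -> 2/3; class3: 0
  expect_equal(f1_similarity(ref, one_hot(pred)), mean(c(1, 2 / 3, 0)))
})

test_that("f1 similarity is invariant under joint class relabelling", {
  perm <- c(3L, 1L, 2L)
  relabel <- function(m) {
    l <- m$labels
    l[l > 0] <- perm[l[l > 0]]
    label_map(l, K = 3)
  }
  for (seed in 1:5) {
    ref <- random_label_map(6, 6, 3, seed = 50 + seed)
    pred <- random_label_map(6, 6, 3, seed = 60 + seed)
    s1 <- f1_similarity(ref, one_hot(pred))
    expect_equal(f1_similarity(relabel(ref), one_hot(relabel(pred))), s1,
                 tolerance = 1e-12)
  }
})

test_that("weighted atlas reduces to the prior atlas under equal weights", {
  # identical candidates: all similarities equal, full selection
  base <- random_label_map(5, 5, 3, 70, p_fg = 1)
  maps <- lapply(1:4, function(j) {
    lm <- base; lm$id <- sprintf("m%d", j); lm
  })
  pred <- random_prob_map(5, 5, 3, 75, p_fg = 1)
  wa <- weighted_atlas(maps, pred, m_w = 10)
  expect_equal(wa$probs, prior_atlas(maps)$probs, tolerance = 1e-12)
  # all-zero similarities: unweighted-mean fallback over the selection,
  # which at full selection is again the prior atlas
  disjoint <- lapply(1:4, function(j)
    random_label_map(5, 5, 5, 70 + j, p_fg = 1, id = sprintf("d%d", j)))
  disjoint <- lapply(disjoint, function(lm) {
    l <- lm$labels; l[l == 5L] <- 1L
    label_map(l, K = 5, id = lm$id)
  })
  only5 <- prob_map(array(rep(c(0, 0, 0, 0, 1), each = 25), c(5, 5, 5)))
  wz <- weighted_atlas(disjoint, only5, m_w = 10)
  expect_true(all(wz$provenance$similarity == 0))
  expect_equal(wz$probs, prior_atlas(disjoint)$probs, tolerance = 1e-12)
})

test_that("weighted atlas with m_w = 1 returns the best candidate's one-hot", {
  maps <- lapply(1:4, function(j) random_label_map(6, 6, 3, 80 + j))
  pred <- one_hot(maps[[3]])
  wa <- weighted_atlas(maps, pred, m_w = 1)
  expect_equal(wa$probs, one_hot(maps[[3]])$probs, tolerance = 1e-12)
  expect_equal(wa$provenance$id, "map0003")
})

test_that("weighted atlas matches the brute-force oracle and honours exclusion", {
  for (seed in 1:6) {
    maps <- lapply(1:6, function(j)
      random_label_map(6, 5, 3, 90 + seed * 7 + j, id = sprintf("c%02d", j)))
    pred <- random_prob_map(6, 5, 3, 200 + seed)
    wa <- weighted_atlas(maps, pred, m_w = 3)
    expect_equal(wa$probs, oracle_weighted_atlas(maps, pred, 3),
                 tolerance = 1e-12)
    wx <- weighted_atlas(maps, pred, m_w = 3, exclude = "c02")
    expect_equal(wx$probs, oracle_weighted_atlas(maps, pred, 3, "c02"),
                 tolerance = 1e-12)
    expect_false("c02" %in% wx$provenance$id)
    s <- apply(wa$probs, c(1, 2), sum)
    expect_true(all(abs(s - 1) < 1e-6))
  }
  maps <- list(random_label_map(4, 4, 2, 1, id = "only"))
  expect_error(weighted_atlas(maps, random_prob_map(4, 4, 2, 2), 1,
                              exclude = "only"), "empty candidate pool")
})

test_that("weighted atlas is invariant to candidate order", {
  maps <- lapply(1:6, function(j)
    random_label_map(6, 5, 3, 300 + j, id = sprintf("c%02d", j)))
  pred <- random_prob_map(6, 5, 3, 301)
  wa1 <- weighted_atlas(maps, pred, m_w = 3)
  wa2 <- weighted_atlas(rev(maps), pred, m_w = 3)
  expect_equal(wa1$probs, wa2$probs, tolerance = 1e-12)
  expect_equal(sort(wa1$provenance$id), sort(wa2$provenance$id))
})
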