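test_that("Dice: identical, disjoint, and hand-counted toy maps", {
  lm <- random_label_map(6, 6, 3, seed = 1)
  d <- dice(lm, lm)
  expect_true(all(d[!is.na(d)] == 1))
  a <- label_map(matrix(c(1L, 1L, 0L, 0L), 1, 4), K = 2)
  b <- label_map(matrix(c(0L, 0L, 1L, 1L), 1, 4), K = 2)
  expect_equal(unname(dice(a, b)[1]), 0)
  # 4x4 toy: reference class 1 covers 8 cells, prediction covers 6,
  # 4 overlapping -> 2*4 / (8+6) = 4/7
  ref <- label_map(rbind(matrix(1L, 2, 4), matrix(2L, 2, 4)), K = 2)
  pred <- label_map(rbind(matrix(2L, 1, 4), matrix(1L, 1, 4),
                          cbind(matrix(1L, 1, 2), matrix(2L, 1, 2)),
                          matrix(2L, 1, 4)), K = 2)
  expect_equal(unname(dice(ref, pred)[1]), 4 / 7)
  # classes absent from the reference are flagged, not scored
  sparse <- label_map(matrix(c(1L, 1L, 1L, 1L), 2, 2), K = 3)
  expect_true(is.na(dice(sparse, sparse)[2]))
})

test_that("Dice is symmetric for classes present on both sides", {
  for (seed in 1:8) {
    a <- random_label_map(7, 6, 3, seed = 600 + seed, p_fg = 1)
    b <- random_label_map(7, 6, 3, seed = 700 + seed, p_fg = 1)
    expect_equal(unname(dice(a, b)), unname(dice(b, a)), tolerance = 1e-12)
  }
})

test_that("quadratic score closed forms: perfect, uniform, maximally wrong", {
  lm <- random_label_map(6, 6, 5, seed = 3, p_fg = 1)
  expect_equal(quadratic_score(one_hot(lm), lm), 1)
  unif <- prob_map(array(0.2, c(6, 6, 5)))
  expect_equal(quadratic_score(unif, lm), 0.2)
  wrong <- label_map(matrix(ifelse(lm$labels == 5L, 1L, lm$labels + 1L),
                            6, 6), K = 5)
  expect_equal(quadratic_score(one_hot(wrong), lm), -1)
})

test_that("confusion matrix matches the loop oracle and its marginals", {
  for (seed in 1:8) {
    ref <- random_label_map(8, 6, 4, seed = 800 + seed, p_fg = 1)
    pred <- random_label_map(8, 6, 4, seed = 900 + seed, p_fg = 1)
    cm <- confusion(ref, pred)
    expect_equal(unname(cm), unname(oracle_confusion(ref, pred)))
    expect_equal(sum(cm), sum(ref$foreground & pred$foreground))
    # row sums are the per-class reference region sizes
    expect_equal(unname(rowSums(cm)),
                 sapply(1:4, function(k) sum(ref$labels == k)))
  }
  # identical maps give a diagonal matrix with trace = foreground size
  lm <- random_label_map(6, 6, 3, seed = 5)
  cm <- confusion(lm, lm)
  expect_equal(sum(diag(cm)), sum(lm$foreground))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  # constant prediction puts all mass in one column
  const <- label_map(matrix(1L, 6, 6), K = 3)
  expect_equal(sum(confusion(lm, const)[, 1]), sum(lm$foreground))
})

test_that("Dice is recomputable from the confusion matrix", {
  for (seed in 1:5) {
    ref <- random_label_map(9, 7, 5, seed = 40 + seed, p_fg = 1)
    pred <- random_label_map(9, 7, 5, seed = 50 + seed, p_fg = 1)
    cm <- confusion(ref, pred)
    from_cm <- 2 * diag(cm) / (rowSums(cm) + colSums(cm))
    d <- dice(ref, pred)
    present <- !is.na(d)
    expect_equal(unname(d[present]), unname(from_cm[present]),
                 tolerance = 1e-12)
  }
})

test_that("cross-validation is deterministic and covers every image once", {
  ds <- generate_dataset(9, seed = 31, grid = c(48, 24))
  cv1 <- cross_validate(ds, tiny_variant(), folds = 3, seed = 5)
  cv2 <- cross_validate(ds, tiny_variant(), folds = 3, seed = 5)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$dice, cv2$dice)
  expect_identical(cv1$confusion, cv2$confusion)
  expect_equal(sort(table(cv1$fold)), sort(table(rep(1:3, 3))),
               ignore_attr = TRUE)
  # one dice row per image and class; absent classes are NA
  expect_equal(nrow(cv1$dice), 9 * 5)
  present <- !is.na(cv1$dice$dice)
  expected_rows <- sum(as.matrix(ds$manifest[, ds$samples[[1]]$labels$class_names]))
  expect_equal(sum(present), expected_rows)
  # quadratic scores are proper-score bounded
  expect_true(all(cv1$quadratic$score >= -1 & cv1$quadratic$score <= 1))
  # leave-one-out degenerate case runs
  small <- generate_dataset(4, seed = 32, grid = c(48, 24))
  cv_loo <- cross_validate(small, tiny_variant(), folds = 4, seed = 1)
  expect_equal(max(cv_loo$fold), 4)
})
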