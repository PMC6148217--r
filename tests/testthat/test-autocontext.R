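# Shared tiny training set for the model-level tests.
ac_ds <- generate_dataset(6, seed = 100, grid = c(48, 24))

test_that("stratified location sampling is balanced and deterministic", {
  maps <- lapply(ac_ds$samples, `[[`, "labels")
  locs <- sample_training_locations(maps, per_class = 40, seed = 3)
  expect_equal(nrow(locs), 5 * 40)
  expect_equal(unname(table(locs$label)), rep(40L, 5), ignore_attr = TRUE)
  # sampled labels agree with the maps they point into
  agree <- mapply(function(m, r, c, l) maps[[m]]$labels[r, c] == l,
                  locs$map, locs$row, locs$col, locs$label)
  expect_true(all(agree))
  locs2 <- sample_training_locations(maps, per_class = 40, seed = 3)
  expect_identical(locs, locs2)
  expect_false(identical(
    locs, sample_training_locations(maps, per_class = 40, seed = 4)))
  # per_class = 1 gives one location per class
  one <- sample_training_locations(maps, per_class = 1, seed = 1)
  expect_equal(nrow(one), 5)
  # a class absent from the whole pool is a stratification error
  hollow <- lapply(maps, function(m) {
    m$labels[m$labels == 2L] <- 3L
    label_map(m$labels, K = 5)
  })
  expect_error(sample_training_locations(hollow, 5, 1),
               "stratification.*heart")
  # the cross-validation harness keeps degenerate folds with a warning
  expect_warning(locs3 <- sample_training_locations(hollow, 5, 1,
                                                    allow_missing = TRUE),
                 "stratification.*heart")
  expect_equal(sort(unique(locs3$label)), c(1L, 3L, 4L, 5L))
})

test_that("feature vector lengths match the published block sizes", {
  fg <- appearance_features(ac_ds$samples[[1]]$image,
                            decomposition_config(subsample_factor = 1))
  expect_equal(dim(fg)[3], 36)
  lm <- ac_ds$samples[[1]]$labels
  pm <- one_hot(lm)
  loc <- which(lm$foreground, arr.ind = TRUE)[10, ]
  v_ac <- assemble_features(fg, pm, location = loc,
                            variant = variant_config("ac"))
  expect_length(v_ac, 36 + 455)
  v_ic <- assemble_features(fg, pm, location = loc,
                            variant = variant_config("ac+ic"))
  expect_length(v_ic, 36 + 455 + 10)
  atl <- prior_atlas(list(lm, ac_ds$samples[[2]]$labels))
  v_all <- assemble_features(fg, pm, atl, loc,
                             variant = variant_config("waac+ic"))
  expect_length(v_all, 36 + 455 + 10 + 455)
  expect_error(assemble_features(fg, pm, NULL, loc,
                                 variant = variant_config("waac")),
               "requires a weighted atlas")
  # centre-only stencil on a uniform map: the stencil block is uniform
  unif <- prob_map(array(0.2, c(48, 24, 5)), lm$foreground)
  v0 <- assemble_features(fg, unif, location = loc,
                          variant = variant_config(
                            "ac", stencil = star_stencil(1, integer(0))))
  expect_equal(unname(v0[37:41]), rep(0.2, 5))
})

test_that("training is deterministic and improves on the prior-atlas baseline", {
  cfg <- tiny_variant("ac+ic", seed = 42)
  m1 <- autocontext(ac_ds, variant = cfg)
  m2 <- autocontext(ac_ds, variant = cfg)
  expect_identical(m1$classifiers[[1]]$weights, m2$classifiers[[1]]$weights)
  expect_identical(m1$history, m2$history)
  # the fitted sequence beats arg-max of the prior atlas on training data
  base_acc <- mean(sapply(ac_ds$samples, function(s) {
    b <- prob_map(m1$prior$probs, s$mask, normalize = TRUE)
    foreground_accuracy(s$labels, argmax_labels(b))
  }))
  expect_gt(tail(m1$history$train_accuracy, 1), base_acc)
})

test_that("with T = 1 a WAAC model is exactly a plain AC model", {
  ac <- autocontext(ac_ds, variant = tiny_variant("ac", seed = 9, T = 1))
  waac <- autocontext(ac_ds, variant = tiny_variant("waac", seed = 9, T = 1))
  expect_identical(ac$classifiers[[1]]$weights,
                   waac$classifiers[[1]]$weights)
  expect_identical(ac$history, waac$history)
})

test_that("prediction returns one valid probability map per iteration", {
  m <- autocontext(ac_ds, variant = tiny_variant("waac+ic", seed = 13))
  s <- generate_pluck(pluck_params(grid = c(48, 24), seed = 999))
  pred <- predict(m, s, all_iterations = TRUE)
  expect_length(pred$iterations, m$variant$T)
  for (pm in pred$iterations) {
    mat <- matrix(pm$probs, prod(dim(pm$probs)[1:2]), 5)
    expect_true(all(abs(rowSums(mat) - 1) < 1e-6))
    expect_identical(pm$foreground, s$mask)
  }
  expect_length(pred$atlases, m$variant$T)
  lab <- predict(m, s, type = "label")
  expect_s3_class(lab, "label_map")
  expect_true(all(lab$labels[!s$mask] == 0L))
})

test_that("an exact twin in the candidate pool dominates the final atlas", {
  # two structurally distinct plucks, several near-duplicates of each in
  # the pool; the weighted atlas must lock onto the right twin family
  twin_a <- generate_pluck(pluck_params(grid = c(48, 24), orientation = 0,
                                        seed = 51))
  twin_b <- generate_pluck(pluck_params(grid = c(48, 24), orientation = 0.9,
                                        seed = 52))
  pool <- c(lapply(1:4, function(i) {
    lm <- twin_a$labels; lm$id <- sprintf("a%02d", i); lm
  }), lapply(1:4, function(i) {
    lm <- twin_b$labels; lm$id <- sprintf("b%02d", i); lm
  }))
  wa <- weighted_atlas(pool, one_hot(twin_a$labels), m_w = 4)
  agree <- mean(argmax_labels(wa)$labels[twin_a$mask] ==
                  twin_a$labels$labels[twin_a$mask])
  expect_gte(agree, 0.99)
  expect_true(all(grepl("^a", wa$provenance$id)))
})

test_that("training pixel accuracy is non-decreasing in the median over seeds", {
  ds <- generate_dataset(6, seed = 201, grid = c(48, 24))
  hist <- sapply(1:10, function(seed) {
    m <- autocontext(ds, variant = variant_config(
      "ac", T = 3, per_class = 150, maxit = 80,
      stencil = star_stencil(8, c(2, 4, 7)), seed = seed))
    m$history$train_accuracy
  })
  med <- apply(hist, 1, median)
  expect_true(all(diff(med) >= -1e-9))
})
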