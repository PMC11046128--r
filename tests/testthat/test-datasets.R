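test_that("the augmentation group has size 8 with an identity element", {
  cr <- make_crop(side = 16L)
  cr$pixels[, , 1] <- matrix(runif(256), 16, 16)  # break symmetry
  aug <- augment8(list(cr))
  expect_length(aug, 8L)
  expect_identical(vapply(aug, `[[`, integer(1), "transform_id"), 0:7)
  expect_identical(aug[[1]]$pixels, cr$pixels)    # transform 0 is identity
  # all 8 transforms are distinct images
  keys <- vapply(aug, function(a) paste(a$pixels[, , 1], collapse = ","),
                 character(1))
  expect_equal(length(unique(keys)), 8L)
})

test_that("augmenting 221 crops yields exactly 1768 images", {
  crops <- lapply(seq_len(221), function(i)
    make_crop(side = 8L, a = 3, b = 2, cell_id = sprintf("c%03d", i)))
  expect_length(augment8(crops), 1768L)
})

test_that("four quarter-rotations recompose the original image", {
  m <- matrix(runif(64), 8, 8)
  r <- m
  for (k in 1:4) r <- apply_transform_matrix(r, 1L)
  expect_identical(r, m)
  # mirror twice is also the identity
  expect_identical(apply_transform_matrix(apply_transform_matrix(m, 4L), 4L),
                   m)
  expect_error(apply_transform_matrix(matrix(0, 4, 6), 1L), "square")
})

test_that("group building follows the three sampling regimes", {
  ko_big <- sprintf("k%04d", 1:4323)
  ctrl <- sprintf("n%04d", 1:5000)
  g1 <- build_group(ko_big, ctrl, target = 3000, seed = 1)
  expect_equal(sum(g1$label == "knockout"), 3000L)
  expect_equal(sum(g1$label == "control"), 3000L)
  expect_true(all(g1$transform_id[g1$label == "knockout"] == 0L))

  ko_mid <- sprintf("k%04d", 1:375)
  g2 <- build_group(ko_mid, ctrl, target = 3000, seed = 1)
  expect_equal(sum(g2$label == "knockout"), 3000L)  # 375 x 8 exactly
  expect_setequal(unique(g2$transform_id[g2$label == "knockout"]), 0:7)

  ko_small <- sprintf("k%04d", 1:221)
  g3 <- build_group(ko_small, ctrl, target = 3000, seed = 1)
  expect_equal(sum(g3$label == "knockout"), 1768L)  # all 8 x 221 kept
  expect_equal(sum(g3$label == "control"), 1768L)   # control reduced to match
})

test_that("an insufficient control pool fails with the shortfall named", {
  expect_error(build_group(sprintf("k%d", 1:100), sprintf("n%d", 1:10),
                           target = 400, seed = 1),
               "shortfall")
})

test_that("the control draw is shared across genes via the control seed", {
  ctrl <- sprintf("n%04d", 1:2000)
  gA <- build_group(sprintf("a%d", 1:1500), ctrl, target = 1000, seed = 5,
                    control_seed = 99)
  gB <- build_group(sprintf("b%d", 1:1500), ctrl, target = 1000, seed = 6,
                    control_seed = 99)
  expect_identical(gA[gA$label == "control", c("cell_id", "transform_id")],
                   gB[gB$label == "control", c("cell_id", "transform_id")])
  # different knockout draws
  expect_false(identical(gA$cell_id[gA$label == "knockout"],
                         gB$cell_id[gB$label == "knockout"]))
})

test_that("splits hit the 80/10/10 quotas without source-cell leakage", {
  ko <- sprintf("k%04d", 1:375)
  ctrl <- sprintf("n%04d", 1:375)
  g <- build_group(ko, ctrl, target = 3000, seed = 2)
  ds <- split_dataset(g, seed = 3, gene_id = "G", channel = "mitochondria")
  m <- ds$members
  expect_equal(as.integer(table(m$split)[c("train", "val", "test")]),
               c(4800L, 600L, 600L))
  # balance within every split
  tab <- table(m$split, m$label)
  expect_true(all(abs(tab[, "knockout"] - tab[, "control"]) <= 8))
  # no-leakage: every source cell lives in exactly one split
  per_cell <- tapply(m$split, m$cell_id, function(s) length(unique(s)))
  expect_true(all(per_cell == 1L))
  # each (cell, transform) pair appears exactly once
  expect_false(anyDuplicated(m[, c("cell_id", "transform_id", "label")]) > 0)
})

test_that("splitting is deterministic per seed and varies across seeds", {
  g <- build_group(sprintf("k%d", 1:500), sprintf("n%d", 1:500),
                   target = 400, seed = 4)
  d1 <- split_dataset(g, seed = 10)
  d2 <- split_dataset(g, seed = 10)
  d3 <- split_dataset(g, seed = 11)
  expect_identical(d1$members, d2$members)
  expect_false(identical(d1$members$split, d3$members$split))
  expect_equal(table(d3$members$split), table(d1$members$split))
  expect_error(split_dataset(g, fractions = c(0.8, 0.1, 0.2)), "sum to 1")
})

test_that("materialization applies transforms and per-image normalization", {
  crops <- lapply(1:6, function(i) {
    cr <- make_crop(side = 16L, cell_id = sprintf("c%d", i),
                    line_id = if (i <= 3) "ko" else "ctrl")
    cr$pixels[, , 5] <- matrix(runif(256), 16, 16)
    cr
  })
  store <- stats::setNames(crops, sprintf("c%d", 1:6))
  g <- build_group(sprintf("c%d", 1:3), sprintf("c%d", 4:6), target = 24,
                   seed = 1)
  ds <- split_dataset(g, fractions = c(0.5, 0.25, 0.25), seed = 1,
                      gene_id = "G", channel = "mitochondria")
  tr <- materialize_split(ds, store, "train")
  expect_equal(ncol(tr$x), 256L)
  expect_equal(length(tr$y), nrow(tr$x))
  expect_true(all(abs(rowMeans(tr$x)) < 1e-8))
  sds <- apply(tr$x, 1, stats::sd)
  expect_true(all(abs(sds - 1) < 1e-3))
})
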