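test_that("compute_auc reproduces hand-countable cases", {
  expect_equal(compute_auc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(compute_auc(c(0.5, 0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(compute_auc(c(0.9, 0.4, 0.6), c(0.5, 0.3, 0.1)), 8 / 9)
  expect_error(compute_auc(numeric(0), c(0.1)), "nonempty")
  expect_error(compute_auc(c(0.1), numeric(0)), "nonempty")
})

test_that("compute_auc equals brute-force pair counting on random scores", {
  set.seed(41)
  for (i in 1:50) {
    np <- sample(1:40, 1)
    nn <- sample(1:40, 1)
    # coarse grid induces plenty of ties
    pos <- sample(seq(0, 1, by = 0.1), np, replace = TRUE)
    neg <- sample(seq(0, 1, by = 0.1), nn, replace = TRUE)
    expect_equal(compute_auc(pos, neg), auc_oracle(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("swapping the classes maps auc to 1 - auc", {
  set.seed(42)
  for (i in 1:20) {
    pos <- runif(sample(2:30, 1))
    neg <- runif(sample(2:30, 1))
    expect_equal(compute_auc(pos, neg), 1 - compute_auc(neg, pos),
                 tolerance = 1e-12)
  }
})

test_that("training selects the best validation epoch on separable data", {
  tr <- toy_image_set(120, seed = 1)
  va <- toy_image_set(30, seed = 2)
  te <- toy_image_set(30, seed = 3)
  cfg <- train_config(epochs = 8, learning_rate = 1e-3, batch_size = 32,
                      seed = 7)
  m <- train_classifier(tr, va, cfg)
  expect_lte(m$selected_epoch, 8L)
  expect_lte(m$val_loss[m$selected_epoch], m$val_loss[1])
  expect_equal(m$val_loss[m$selected_epoch], min(m$val_loss))
  ev <- evaluate_auc(m, te)
  expect_gte(ev$auc, 0.9)
  expect_equal(ev$n_test_pos, 30L)
  # determinism for a fixed seed; different seed changes the fit
  m2 <- train_classifier(tr, va, cfg)
  expect_identical(m$weights, m2$weights)
  m3 <- train_classifier(tr, va, train_config(epochs = 8,
                                              learning_rate = 1e-3,
                                              batch_size = 32, seed = 8))
  expect_false(identical(m$weights, m3$weights))
})

test_that("prediction is deterministic, bounded and order-preserving", {
  tr <- toy_image_set(40, seed = 4)
  va <- toy_image_set(10, seed = 5)
  m <- train_classifier(tr, va, train_config(epochs = 2, learning_rate = 1e-3,
                                             seed = 1))
  s1 <- predict_scores(m, va$x)
  s2 <- predict_scores(m, va$x)
  expect_identical(s1, s2)
  expect_length(s1, nrow(va$x))
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_identical(s1[3], predict_scores(m, va$x[3, , drop = FALSE]))
  expect_error(predict_scores(m, va$x[, 1:100]), "pixels per image")
})

test_that("empty splits and malformed inputs are rejected", {
  tr <- toy_image_set(10, seed = 6)
  expect_error(train_classifier(list(x = tr$x[0, ], y = integer(0)), tr),
               "empty training split")
  expect_error(train_classifier(tr, list(x = tr$x[0, ], y = integer(0))),
               "empty validation split")
  bad <- list(x = tr$x[, 1:1000], y = tr$y)   # not a square image
  expect_error(train_classifier(bad, tr), "square")
})

test_that("shuffled labels keep the test AUC at chance level", {
  aucs <- vapply(1:10, function(s) {
    set.seed(900 + s)
    tr <- toy_image_set(150, seed = 100 + s)
    tr$y <- sample(tr$y)              # destroy the signal
    va <- toy_image_set(40, seed = 200 + s)
    va$y <- sample(va$y)
    te <- toy_image_set(80, seed = 300 + s)
    te$y <- sample(te$y)
    m <- train_classifier(tr, va, train_config(epochs = 3,
                                               learning_rate = 1e-3,
                                               seed = s))
    evaluate_auc(m, te)$auc
  }, numeric(1))
  expect_true(all(aucs >= 0.40 & aucs <= 0.60))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})
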