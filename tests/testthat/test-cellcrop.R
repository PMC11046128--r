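test_that("blank and malformed fields are handled at segmentation", {
  blank <- array(0, c(128, 128, 5))
  expect_equal(max(segment_field(blank, small_params())), 0)
  expect_error(segment_field(array(0, c(64, 64, 3))), "5 channels")
})

test_that("well-separated planted cells are each recovered as one mask", {
  geom <- small_geom(cells = 5L)
  f <- render_field(perturbation_spec("ctrl"), seed = 11, geom = geom)
  m <- segment_field(f, small_params())
  expect_equal(max(m), 5L)
  labs_at_centroids <- m[cbind(round(f$truth$row), round(f$truth$col))]
  expect_setequal(labs_at_centroids, 1:5)  # each centroid in its own mask
  expect_equal(sort(unique(as.vector(m))), 0:5)  # labels dense from 1
})

test_that("segmentation recall and precision exceed 0.95 on simulated fields", {
  geom <- small_geom(cells = 12L)
  hits <- 0L
  planted <- 0L
  found <- 0L
  for (s in 1:8) {
    f <- render_field(perturbation_spec("ctrl"), seed = 200 + s, geom = geom)
    m <- segment_field(f, small_params())
    labs <- m[cbind(round(f$truth$row), round(f$truth$col))]
    planted <- planted + nrow(f$truth)
    found <- found + max(m)
    hits <- hits + length(unique(labs[labs > 0]))
  }
  expect_gte(hits / planted, 0.95)  # recall
  expect_gte(hits / found, 0.95)    # precision
})

test_that("specks below the area bound are excluded", {
  px <- array(0, c(128, 128, 5))
  px[60:62, 60:62, 1] <- 0.9   # 3x3 nucleus-channel speck
  m <- segment_field(px, small_params())
  expect_equal(max(m), 0)
})

test_that("crops share one box across channels and zero out neighbours", {
  geom <- small_geom(cells = 6L)
  f <- render_field(perturbation_spec("ctrl"), seed = 21, geom = geom)
  m <- segment_field(f, small_params())
  cc <- crop_cells(f, m, side = 32L, params = small_params())
  expect_equal(length(cc$crops), sum(cc$flags$pass))
  for (cr in cc$crops) {
    expect_equal(dim(cr$pixels), c(32L, 32L, 5L))
    # all pixels outside the (shared) mask are exactly zero in all channels
    for (ch in 1:5) expect_true(all(cr$pixels[, , ch][!cr$mask] == 0))
    # box is half-open and in-bounds
    expect_true(cr$bbox["r0"] >= 0 && cr$bbox["r1"] <= dim(f$pixels)[1])
    expect_true(cr$bbox["r1"] > cr$bbox["r0"])
  }
})

test_that("border-touching cells are flagged and not cropped", {
  px <- array(0, c(128, 128, 5))
  dr <- matrix(seq_len(128), 128, 128)
  dc <- t(dr)
  disk <- (dr - 4)^2 + (dc - 64)^2 <= 12^2   # nucleus at the top border
  body <- (dr - 4)^2 + (dc - 64)^2 <= 20^2
  px[, , 1][disk] <- 0.8
  px[, , 4][body] <- 0.4
  f <- as_field(px)
  params <- segment_params(cell_radius = 13)
  m <- segment_field(f, params)
  cc <- crop_cells(f, m, side = 32L, params = params)
  expect_true(any(cc$flags$touches_border))
  expect_equal(length(cc$crops), 0L)
})

test_that("feature extraction is deterministic and schema-complete", {
  cr <- make_crop(values = c(0.5, 0.2, 0.3, 0.4, 0.6))
  v1 <- extract_features(cr)
  v2 <- extract_features(cr)
  expect_identical(v1, v2)
  expect_identical(names(v1), feature_schema())
  expect_length(v1, 29L)
  expect_true(all(is.finite(v1)))
  # uniform intensity inside the mask: zero standard deviation
  expect_equal(unname(v1["sd_nucleus"]), 0)
  expect_equal(unname(v1["mean_nucleus"]), 0.5)
})

test_that("mask area matches the analytic ellipse area within 5 percent", {
  cr <- make_crop(side = 64L, a = 20, b = 10)
  v <- extract_features(cr)
  expect_lt(abs(v["area"] - pi * 20 * 10) / (pi * 20 * 10), 0.05)
  # downscaled crop reports area in field-pixel units
  cr2 <- make_crop(side = 64L, a = 20, b = 10, scale = 2)
  expect_equal(unname(extract_features(cr2)["area"]),
               unname(4 * v["area"]))
})

test_that("degenerate masks raise an error", {
  cr <- make_crop()
  cr$mask[] <- FALSE
  expect_error(extract_features(cr), "degenerate mask")
})

test_that("feature table carries identity and ground-truth columns", {
  crops <- list(make_crop(cell_id = "a", line_id = "L1"),
                make_crop(cell_id = "b", line_id = "L2"))
  ft <- feature_table(crops)
  expect_equal(ft$cell_id, c("a", "b"))
  expect_equal(ft$line_id, c("L1", "L2"))
  expect_identical(setdiff(names(ft), c("cell_id", "line_id", "truth_outlier")),
                   feature_schema())
})
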