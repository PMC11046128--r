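# Shared fixtures: small-geometry fields and hand-built crops. Everything is
# generated in code at test time; no stored image data.

small_geom <- function(cells = 12L, size = 192L) {
  field_geometry(field_size = size, cell_radius = 13, cells_per_field = cells,
                 noise_sd = 0.008)
}

small_params <- function() segment_params(cell_radius = 13)

# a bare FieldImage around a given pixel array
as_field <- function(pixels, line_id = "L1", plate = "P1", well = "A01",
                     site = 1L, truth = NULL) {
  structure(list(pixels = pixels, plate = plate, well = well,
                 site = as.integer(site), line_id = line_id, truth = truth),
            class = "FieldImage")
}

# a bare CellCrop with a centred elliptical mask
make_crop <- function(side = 32L, a = 10, b = 6, values = NULL,
                      cell_id = "cell1", line_id = "L1", scale = 1) {
  ctr <- (side + 1) / 2
  dr <- matrix(seq_len(side) - ctr, side, side)
  dc <- t(dr)
  mask <- (dc / a)^2 + (dr / b)^2 <= 1
  px <- array(0, c(side, side, 5))
  if (is.null(values)) values <- seq(0.2, 0.6, length.out = 5)
  for (ch in 1:5) px[, , ch] <- values[ch] * mask
  structure(list(pixels = px, mask = mask, cell_id = cell_id,
                 line_id = line_id, plate = "P1", well = "A01", site = 1L,
                 bbox = c(0L, side, 0L, side), scale = scale,
                 truth_outlier = NA),
            class = "CellCrop")
}

# random feature table for QC property tests
random_feature_table <- function(n_cells, n_feat = 8L, lines = "L1",
                                 seed = 1L) {
  set.seed(seed)
  mat <- matrix(stats::rlnorm(n_cells * n_feat, 0, 1), n_cells, n_feat)
  df <- data.frame(cell_id = sprintf("c%03d", seq_len(n_cells)),
                   line_id = rep(lines, length.out = n_cells),
                   stringsAsFactors = FALSE)
  cbind(df, stats::setNames(as.data.frame(mat),
                            sprintf("f%02d", seq_len(n_feat))))
}

# rank-then-Pearson Spearman oracle (midranks)
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))

# brute-force AUC oracle: pair counting with half credit for ties
auc_oracle <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# separable toy image set for classifier tests: noise vs noise + offset blob
toy_image_set <- function(n_per_class, side = 32L, seed = 1L,
                          strength = 3) {
  set.seed(seed)
  mk <- function(blob) t(vapply(seq_len(n_per_class), function(i) {
    m <- matrix(stats::rnorm(side * side), side, side)
    if (blob) {
      r <- sample(seq(8L, side - 8L), 1)
      c <- sample(seq(8L, side - 8L), 1)
      m[r + (-3:3), c + (-3:3)] <- m[r + (-3:3), c + (-3:3)] + strength
    }
    v <- as.vector(m)
    (v - mean(v)) / stats::sd(v)
  }, numeric(side * side)))
  list(x = rbind(mk(TRUE), mk(FALSE)),
       y = rep(c(1L, 0L), each = n_per_class))
}
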