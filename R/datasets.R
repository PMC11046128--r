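#' The 8-transform geometric augmentation group
#'
#' Rotations by 0/90/180/270 degrees crossed with optional horizontal
#' mirroring: `transform_id = rotation_index + 4 * mirror`, so id 0 is the
#' identity. Mirroring, when requested, is applied before the rotation.
#'
#' @param m Square matrix (one image channel).
#' @param transform_id Integer 0-7.
#' @return Transformed matrix of the same shape.
#' @export
apply_transform_matrix <- function(m, transform_id) {
  stopifnot(transform_id %in% 0:7)
  if (nrow(m) != ncol(m)) stop("rotation augmentation requires square images")
  if (transform_id >= 4L) m <- m[, rev(seq_len(ncol(m)))]
  for (k in seq_len(transform_id %% 4L)) {
    m <- t(m)[rev(seq_len(ncol(m))), ]   # 90 degrees counter-clockwise
  }
  m
}

#' @rdname apply_transform_matrix
#' @param crop A `CellCrop` (all channels transformed with the same id).
#' @export
apply_transform <- function(crop, transform_id) {
  stopifnot(inherits(crop, "CellCrop"))
  px <- crop$pixels
  if (dim(px)[1] != dim(px)[2]) stop("rotation augmentation requires square crops")
  for (ch in seq_len(dim(px)[3])) {
    px[, , ch] <- apply_transform_matrix(crop$pixels[, , ch], transform_id)
  }
  out <- crop
  out$pixels <- px
  out$mask <- apply_transform_matrix(crop$mask, transform_id)
  out$transform_id <- as.integer(transform_id)
  out
}

#' Expand crops by the full augmentation group
#'
#' @param crops List of square `CellCrop` objects.
#' @return List of `8 * length(crops)` crops, each tagged with `transform_id`
#'   (0 = the unmodified crop), ordered crop-major.
#' @export
augment8 <- function(crops) {
  out <- vector("list", 8L * length(crops))
  k <- 0L
  for (cr in crops) {
    for (tid in 0:7) {
      k <- k + 1L
      out[[k]] <- apply_transform(cr, tid)
    }
  }
  out
}

#' Build one balanced knockout-vs-control member list
#'
#' Assembles the image set for one gene comparison at a target size (3000 in
#' the full-scale screen). Knockout side: with at least `target` post-QC cells,
#' `target` unaugmented cells are sampled; with fewer (but at least
#' `target / 8`), the cells are 8-fold augmented and subsampled to `target`;
#' with fewer still, all `8 * raw` augmented images are kept and the control
#' side is reduced to match, preserving the 50:50 balance. The control side is
#' drawn with its own screen-wide seed so the same control images are chosen
#' for every knockout comparison in a screen.
#'
#' @param knockout_ids,control_ids Character vectors of post-QC cell ids.
#' @param target Target images per side (default 3000).
#' @param seed Replicate seed for the knockout-side sampling.
#' @param control_seed Screen-wide seed for the control-side sampling
#'   (defaults to `seed`; hold it fixed across genes).
#' @return data.frame of members: `cell_id`, `transform_id`, `label`
#'   (`"knockout"`/`"control"`).
#' @export
build_group <- function(knockout_ids, control_ids, target = 3000L, seed = 1L,
                        control_seed = seed) {
  stopifnot(length(knockout_ids) >= 1L, length(control_ids) >= 1L,
            target >= 8L)
  sample_side <- function(ids, n_images, seed) {
    set.seed(as.integer(seed))
    raw <- length(ids)
    if (raw >= n_images) {
      data.frame(cell_id = sample(ids, n_images), transform_id = 0L,
                 stringsAsFactors = FALSE)
    } else {
      full <- data.frame(cell_id = rep(ids, each = 8L),
                         transform_id = rep(0:7, times = raw),
                         stringsAsFactors = FALSE)
      if (nrow(full) < n_images) {
        stop("side with ", raw, " cells cannot reach ", n_images,
             " images even with 8-fold augmentation (shortfall ",
             n_images - nrow(full), ")")
      }
      full[sample.int(nrow(full), n_images), ]
    }
  }
  raw_ko <- length(knockout_ids)
  n_images <- if (raw_ko >= target) as.integer(target) else
    min(as.integer(target), 8L * raw_ko)
  ko <- sample_side(knockout_ids, n_images, mix_seed(seed, 11L))
  if (8L * length(control_ids) < n_images) {
    stop("control pool of ", length(control_ids), " cells cannot supply ",
         n_images, " images (shortfall ",
         n_images - 8L * length(control_ids), ")")
  }
  ctrl <- sample_side(control_ids, n_images, mix_seed(control_seed, 12L))
  ko$label <- "knockout"
  ctrl$label <- "control"
  members <- rbind(ko, ctrl)
  rownames(members) <- NULL
  members
}

#' Split members into train/validation/test at the source-cell level
#'
#' Cells (not images) are partitioned, so every augmented copy of a cell lands
#' in the same split and no source cell leaks across splits. Within each
#' label, cells are shuffled deterministically and assigned greedily to fill
#' the image-count quotas, preserving the 50:50 label balance within rounding.
#'
#' @param members Member data.frame from [build_group()].
#' @param fractions Numeric length-3 train/validation/test fractions summing
#'   to 1.
#' @param seed Replicate seed.
#' @param gene_id,channel Metadata recorded on the dataset.
#' @return A `ScreenDataset`: list with `gene_id`, `channel`,
#'   `replicate_seed` and `members` (with a `split` column).
#' @export
split_dataset <- function(members, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                          gene_id = NA_character_, channel = NA_character_) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be length 3 and sum to 1")
  }
  members$split <- NA_character_
  set.seed(mix_seed(seed, 21L))
  splits <- c("train", "val", "test")
  quota <- stats::setNames(fractions * nrow(members), splits)
  assigned <- stats::setNames(c(0, 0, 0), splits)
  leftover <- list()
  for (lab in unique(members$label)) {
    rows <- which(members$label == lab)
    per_cell <- split(rows, members$cell_id[rows])
    per_cell <- per_cell[sample(length(per_cell))]
    counts <- vapply(per_cell, length, integer(1))
    if (length(unique(counts)) == 1L) {
      # uniform augmentation within the label: floor cell quotas per split,
      # park the remainder cells for deficit-based assignment across labels
      base <- floor(fractions * length(per_cell))
      tags <- rep(splits, base)
      for (k in seq_along(tags)) {
        members$split[per_cell[[k]]] <- tags[k]
        assigned[tags[k]] <- assigned[tags[k]] + counts[k]
      }
      if (length(per_cell) > length(tags)) {
        leftover <- c(leftover, per_cell[(length(tags) + 1L):length(per_cell)])
      }
    } else {
      # mixed 1x/8x cells: greedily fill the label's image-count deficits
      lquota <- stats::setNames(fractions * sum(counts), splits)
      lassigned <- stats::setNames(c(0, 0, 0), splits)
      for (k in seq_along(per_cell)) {
        tgt <- names(which.max(lquota - lassigned))
        members$split[per_cell[[k]]] <- tgt
        lassigned[tgt] <- lassigned[tgt] + counts[k]
        assigned[tgt] <- assigned[tgt] + counts[k]
      }
    }
  }
  for (cell_rows in leftover) {
    tgt <- names(which.max(quota - assigned))
    members$split[cell_rows] <- tgt
    assigned[tgt] <- assigned[tgt] + length(cell_rows)
  }
  structure(
    list(gene_id = gene_id, channel = channel,
         replicate_seed = as.integer(seed), members = members),
    class = "ScreenDataset"
  )
}

#' Materialize a dataset split as an image matrix
#'
#' Resolves member rows against a crop store, extracts the dataset's channel,
#' applies each member's geometric transform and flattens images row-wise.
#' Each image is normalized to zero mean and unit variance, so the classifier
#' sees shape and texture rather than absolute brightness (per-well gain and
#' batch background carry no label information by construction).
#'
#' @param dataset A `ScreenDataset`.
#' @param crop_store Named list of `CellCrop` objects keyed by `cell_id`.
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @param normalize Per-image standardization (default TRUE).
#' @return List with `x` (n x side^2 matrix), `y` (integer 0/1 labels,
#'   knockout = 1) and `side`.
#' @export
materialize_split <- function(dataset, crop_store, split,
                              normalize = TRUE) {
  stopifnot(inherits(dataset, "ScreenDataset"))
  rows <- dataset$members[dataset$members$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop("split '", split, "' is empty")
  ch <- channel_slot(dataset$channel)
  first <- crop_store[[rows$cell_id[1]]]
  if (is.null(first)) stop("cell '", rows$cell_id[1], "' not in crop store")
  side <- dim(first$pixels)[1]
  x <- matrix(0, nrow(rows), side * side)
  for (i in seq_len(nrow(rows))) {
    cr <- crop_store[[rows$cell_id[i]]]
    if (is.null(cr)) stop("cell '", rows$cell_id[i], "' not in crop store")
    m <- apply_transform_matrix(cr$pixels[, , ch], rows$transform_id[i])
    v <- as.vector(m)
    if (normalize) {
      s <- stats::sd(v)
      v <- (v - mean(v)) / (s + 1e-8)
    }
    x[i, ] <- v
  }
  list(x = x, y = as.integer(rows$label == "knockout"), side = side)
}
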