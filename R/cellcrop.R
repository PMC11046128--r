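#' Segmentation parameter set
#'
#' Defaults scale with the nominal cell radius so the same settings work for
#' full-size and scaled-down fields. Area bounds are expressed in field
#' pixels of the cell-body mask.
#'
#' @param cell_radius Nominal cell semi-major axis in pixels.
#' @param min_area,max_area Cell-body area bounds; cells outside are excluded.
#' @param nucleus_blur,body_blur Gaussian sigmas for the seed and body images.
#' @param floor Absolute intensity floor added to the Otsu threshold guard.
#' @return List of segmentation settings.
#' @export
segment_params <- function(cell_radius = 30,
                           min_area = round(0.18 * pi * cell_radius^2),
                           max_area = round(3.5 * pi * cell_radius^2),
                           nucleus_blur = max(1, cell_radius / 10),
                           body_blur = max(1, cell_radius / 8),
                           floor = 0.06, sat_frac = 0.35) {
  list(cell_radius = cell_radius, min_area = min_area, max_area = max_area,
       nucleus_blur = nucleus_blur, body_blur = body_blur, floor = floor,
       sat_frac = sat_frac)
}

#' Segment a field into labelled cell masks
#'
#' CellProfiler-equivalent two-stage segmentation: Otsu thresholding of the
#' blurred nucleus channel yields seed objects, which are expanded over a
#' cytoplasm-signal mask (maximum over the non-nuclear channels) by
#' watershed-style region growing ([EBImage::propagate()]). Cells failing the
#' area bounds are removed and the surviving labels are renumbered densely
#' from 1.
#'
#' @param field A `FieldImage` (or plain H x W x 5 array).
#' @param params A [segment_params()].
#' @return Integer H x W matrix of disjoint cell labels (0 = background).
#' @export
segment_field <- function(field, params = segment_params()) {
  px <- if (inherits(field, "FieldImage")) field$pixels else field
  if (length(dim(px)) != 3L || dim(px)[3] != n_channels()) {
    stop("field must have exactly ", n_channels(), " channels")
  }
  size <- dim(px)[1:2]
  nuc <- px[, , 1]
  if (diff(range(nuc)) < 1e-8) {
    return(matrix(0L, size[1], size[2]))
  }
  nb <- EBImage::gblur(nuc, sigma = params$nucleus_blur)
  thr <- max(EBImage::otsu(EBImage::Image(nb), range = c(0, 1)), params$floor)
  seeds <- EBImage::bwlabel(nb > thr)
  # drop speck seeds well below any plausible nucleus
  seed_area <- tabulate(seeds[seeds > 0])
  tiny <- which(seed_area < max(9, 0.02 * pi * params$cell_radius^2))
  if (length(tiny)) seeds[seeds %in% tiny] <- 0L
  if (max(seeds) == 0) {
    return(matrix(0L, size[1], size[2]))
  }
  body <- EBImage::gblur(pmax(px[, , 2], px[, , 3], px[, , 4], px[, , 5], nuc),
                         sigma = params$body_blur)
  bthr <- max(EBImage::otsu(EBImage::Image(body), range = c(0, 1)) * 0.6,
              params$floor)
  bmask <- EBImage::fillHull(body > bthr | seeds > 0)
  cells <- EBImage::propagate(EBImage::Image(body), seeds, mask = bmask)
  cells <- as.matrix(EBImage::imageData(cells))
  areas <- tabulate(cells[cells > 0])
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, size[1], size[2])
  nz <- cells > 0
  out[nz] <- relab[cells[nz]]
  out
}

crop_quality_flags <- function(sub_mask, sub_px, bbox, size, params) {
  area <- sum(sub_mask)
  sat <- FALSE
  for (ch in seq_len(n_channels())) {
    v <- sub_px[, , ch][sub_mask]
    if (mean(v >= 0.995) > params$sat_frac) { sat <- TRUE; break }
  }
  grad_energy <- 0
  for (ch in seq_len(n_channels())) {
    m <- sub_px[, , ch] * sub_mask
    grad_energy <- grad_energy + mean(abs(diff(m))) + mean(abs(t(diff(t(m)))))
  }
  c(touches_border = bbox[1] == 0 || bbox[3] == 0 ||
      bbox[2] == size[1] || bbox[4] == size[2],
    under_min_area = area < params$min_area,
    over_max_area = area > params$max_area,
    saturated = sat,
    blur_suspect = grad_energy < params$floor / 20)
}

#' Crop single cells from a segmented field
#'
#' Emits one multi-channel `CellCrop` per cell that passes the quality flags.
#' All five channels are cropped with the same bounding box; pixels outside
#' the cell's own mask are zeroed so neighbouring cells cannot leak into the
#' crop (single-cell morphology is then literally the only content of the
#' image). Crops are padded to a square and, only when larger than `side`,
#' scaled down to `side` preserving aspect; the applied scale is recorded so
#' features can be reported in field-pixel units.
#'
#' @param field A `FieldImage`.
#' @param masks Label matrix from [segment_field()].
#' @param side Output crop side in pixels.
#' @param params The [segment_params()] used (supplies area bounds for flags).
#' @return List with `crops` (list of `CellCrop`) and `flags` (data.frame of
#'   `QualityFlag` rows: one per segmented cell, `pass` true iff no flag set).
#' @export
crop_cells <- function(field, masks, side = 96L, params = segment_params()) {
  stopifnot(inherits(field, "FieldImage"))
  px <- field$pixels
  size <- dim(px)[1:2]
  labs <- sort(unique(masks[masks > 0]))
  crops <- list()
  flag_rows <- list()
  truth_lab <- NULL
  if (!is.null(field$truth) && nrow(field$truth)) {
    truth_lab <- masks[cbind(pmin(pmax(round(field$truth$row), 1), size[1]),
                             pmin(pmax(round(field$truth$col), 1), size[2]))]
  }
  fg <- which(masks > 0)
  fg_lab <- masks[fg]
  fg_r <- (fg - 1L) %% size[1] + 1L
  fg_c <- (fg - 1L) %/% size[1] + 1L
  for (lab in labs) {
    sel <- fg_lab == lab
    if (!any(sel)) stop("internal inconsistency: empty mask for label ", lab)
    rr <- range(fg_r[sel])
    cc <- range(fg_c[sel])
    # half-open 0-based box in field coordinates
    bbox <- c(r0 = rr[1] - 1L, r1 = rr[2], c0 = cc[1] - 1L, c1 = cc[2])
    cell_id <- sprintf("%s_%s_s%02d_c%03d", field$plate, field$well,
                       field$site, lab)
    sub_mask0 <- masks[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == lab
    sub_px0 <- px[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE]
    fl <- crop_quality_flags(sub_mask0, sub_px0, bbox, size, params)
    flag_rows[[length(flag_rows) + 1L]] <- data.frame(
      cell_id = cell_id, t(fl), pass = !any(fl), stringsAsFactors = FALSE)
    if (any(fl)) next

    h <- rr[2] - rr[1] + 1L
    w <- cc[2] - cc[1] + 1L
    box_side <- max(h, w)
    sq_mask <- matrix(FALSE, box_side, box_side)
    or <- (box_side - h) %/% 2L
    oc <- (box_side - w) %/% 2L
    sq_mask[or + seq_len(h), oc + seq_len(w)] <- sub_mask0
    sq_px <- array(0, c(box_side, box_side, n_channels()))
    for (ch in seq_len(n_channels())) {
      sq_px[or + seq_len(h), oc + seq_len(w), ch] <- sub_px0[, , ch] * sub_mask0
    }
    scale <- 1
    if (box_side > side) {
      scale <- box_side / side
      res <- array(0, c(side, side, n_channels()))
      for (ch in seq_len(n_channels())) {
        res[, , ch] <- as.matrix(EBImage::resize(EBImage::Image(sq_px[, , ch]),
                                                 w = side, h = side))
      }
      sq_px <- res
      sq_mask <- as.matrix(EBImage::resize(EBImage::Image(sq_mask * 1),
                                           w = side, h = side)) > 0.5
    } else if (box_side < side) {
      pad_px <- array(0, c(side, side, n_channels()))
      pad_mask <- matrix(FALSE, side, side)
      o2r <- (side - box_side) %/% 2L
      o2c <- o2r
      pad_px[o2r + seq_len(box_side), o2c + seq_len(box_side), ] <- sq_px
      pad_mask[o2r + seq_len(box_side), o2c + seq_len(box_side)] <- sq_mask
      sq_px <- pad_px
      sq_mask <- pad_mask
    }
    sq_px[sq_px < 0] <- 0
    truth_outlier <- NA
    if (!is.null(truth_lab)) {
      hit <- which(truth_lab == lab)
      if (length(hit)) truth_outlier <- any(field$truth$outlier[hit])
    }
    crops[[length(crops) + 1L]] <- structure(
      list(pixels = sq_px, mask = sq_mask, cell_id = cell_id,
           line_id = field$line_id, plate = field$plate, well = field$well,
           site = field$site, bbox = bbox, scale = scale,
           truth_outlier = truth_outlier),
      class = "CellCrop"
    )
  }
  flags <- if (length(flag_rows)) do.call(rbind, flag_rows) else
    data.frame(cell_id = character(0), touches_border = logical(0),
               under_min_area = logical(0), over_max_area = logical(0),
               saturated = logical(0), blur_suspect = logical(0),
               pass = logical(0))
  list(crops = crops, flags = flags)
}

#' Fixed per-cell feature schema
#'
#' Per channel: mean, median, standard deviation and integrated intensity
#' inside the cell mask plus mean gradient magnitude; then mask area,
#' perimeter, eccentricity and solidity. 29 features, fixed order, schema
#' version 1.
#'
#' @return Character vector of feature names in schema order.
#' @export
feature_schema <- function() {
  c(as.vector(vapply(channel_names(), function(ch)
    paste0(c("mean_", "median_", "sd_", "integrated_", "gradmag_"), ch),
    character(5))),
    "area", "perimeter", "eccentricity", "solidity")
}

#' Extract the per-cell morphological feature vector
#'
#' Intensity statistics are computed inside the cell mask only (and are
#' therefore invariant to the zeroed background); gradient magnitude uses
#' central differences averaged over the mask interior. Shape features are
#' reported in field-pixel units by undoing any crop downscaling.
#'
#' @param crop A `CellCrop`.
#' @return Named numeric vector following [feature_schema()].
#' @export
extract_features <- function(crop) {
  stopifnot(inherits(crop, "CellCrop"))
  mask <- crop$mask
  area_px <- sum(mask)
  if (area_px < 1) stop("degenerate mask: no foreground pixel")
  n <- nrow(mask)
  inner <- mask
  inner[2:n, ] <- inner[2:n, ] & mask[1:(n - 1), ]
  inner[1:(n - 1), ] <- inner[1:(n - 1), ] & mask[2:n, ]
  inner[, 2:n] <- inner[, 2:n] & mask[, 1:(n - 1)]
  inner[, 1:(n - 1)] <- inner[, 1:(n - 1)] & mask[, 2:n]
  if (!any(inner)) inner <- mask

  vals <- numeric(0)
  for (ch in seq_len(n_channels())) {
    m <- crop$pixels[, , ch]
    v <- m[mask]
    gx <- matrix(0, n, n)
    gy <- matrix(0, n, n)
    gx[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
    gy[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / 2
    gm <- sqrt(gx^2 + gy^2)
    s <- if (length(v) > 1) stats::sd(v) else 0
    vals <- c(vals, mean(v), stats::median(v), s,
              sum(v) * crop$scale^2, mean(gm[inner]))
  }
  shp <- EBImage::computeFeatures.shape(EBImage::Image(mask * 1))
  mom <- EBImage::computeFeatures.moment(EBImage::Image(mask * 1))
  pts <- which(mask, arr.ind = TRUE)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  k <- nrow(hp)
  hull_area <- if (k >= 3) {
    abs(sum(hp[, 1] * hp[c(2:k, 1), 2] - hp[c(2:k, 1), 1] * hp[, 2])) / 2
  } else area_px
  solidity <- min(1, area_px / max(hull_area, 1))
  vals <- c(vals,
            area_px * crop$scale^2,
            shp[1, "s.perimeter"] * crop$scale,
            mom[1, "m.eccentricity"],
            solidity)
  stats::setNames(vals, feature_schema())
}

#' Build the screen feature table
#'
#' @param crops List of `CellCrop` objects.
#' @return data.frame with `cell_id`, `line_id`, a `truth_outlier` column
#'   (ground-truth flag when crops came from simulated fields, otherwise NA)
#'   and one column per feature in [feature_schema()].
#' @export
feature_table <- function(crops) {
  stopifnot(length(crops) > 0)
  mat <- t(vapply(crops, extract_features, numeric(length(feature_schema()))))
  df <- data.frame(
    cell_id = vapply(crops, `[[`, character(1), "cell_id"),
    line_id = vapply(crops, `[[`, character(1), "line_id"),
    truth_outlier = vapply(crops, function(cr)
      as.logical(cr$truth_outlier), logical(1)),
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(mat))
}
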