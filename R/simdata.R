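#' Perturbation specification for one cell line
#'
#' Describes the ground-truth morphological perturbation planted in a
#' simulated cell line: a dimensionless effect size `delta >= 0` per channel
#' (0 everywhere reproduces the control parameterization exactly) and a
#' fraction of cells rendered as degenerate outliers for the QC filter to
#' remove.
#'
#' @param line_id Unique line identifier (e.g. a gene symbol or
#'   "nontargeting_1").
#' @param effects Named numeric vector of per-channel effect sizes; names must
#'   be channel names ([channel_names()]); missing channels default to 0.
#' @param outlier_fraction Proportion in \[0,1\] of planted cells rendered as
#'   outliers.
#' @param outlier_kind One of `"debris"` (autofluorescent high-frequency
#'   speckle whose per-channel brightness inverts the stain pattern — strong
#'   corruption, removable by the Spearman filter), `"saturated"` (uniform
#'   saturated blob) or `"empty"` (near-empty stain).
#' @return A `PerturbationSpec` object; `target_channel` is the channel with
#'   the largest effect (NA if all zero).
#' @export
perturbation_spec <- function(line_id, effects = NULL, outlier_fraction = 0,
                              outlier_kind = c("debris", "saturated", "empty")) {
  stopifnot(is.character(line_id), length(line_id) == 1L, nzchar(line_id))
  outlier_kind <- match.arg(outlier_kind)
  delta <- stats::setNames(numeric(n_channels()), channel_names())
  if (!is.null(effects)) {
    if (is.null(names(effects)) || !all(names(effects) %in% channel_names())) {
      stop("'effects' must be a named vector using channel names: ",
           paste(channel_names(), collapse = ", "))
    }
    if (any(effects < 0) || any(!is.finite(effects))) {
      stop("effect sizes must be finite and >= 0")
    }
    delta[names(effects)] <- effects
  }
  if (!is.numeric(outlier_fraction) || outlier_fraction < 0 || outlier_fraction > 1) {
    stop("'outlier_fraction' must be in [0, 1]")
  }
  target <- if (max(delta) > 0) channel_names()[which.max(delta)] else NA_character_
  structure(
    list(line_id = line_id, delta = delta, target_channel = target,
         outlier_fraction = outlier_fraction, outlier_kind = outlier_kind),
    class = "PerturbationSpec"
  )
}

#' Field rendering geometry
#'
#' @param field_size Side of the square field in pixels (>= 64).
#' @param cell_radius Nominal cell semi-major axis scale in pixels.
#' @param cells_per_field Integer range (length 1 or 2) of cells planted per
#'   field.
#' @param min_sep_factor Minimum centre-to-centre separation between planted
#'   cells, in units of `cell_radius`; the default guarantees non-overlapping
#'   cell bodies.
#' @param noise_sd Standard deviation of additive Gaussian read noise.
#' @return A list of geometry parameters.
#' @export
field_geometry <- function(field_size = 512, cell_radius = 30,
                           cells_per_field = c(8, 40),
                           min_sep_factor = 2.7, noise_sd = 0.008) {
  stopifnot(field_size >= 64, cell_radius >= 4,
            length(cells_per_field) %in% c(1L, 2L), all(cells_per_field >= 1))
  list(field_size = as.integer(field_size), cell_radius = cell_radius,
       cells_per_field = as.integer(cells_per_field),
       min_sep_factor = min_sep_factor, noise_sd = noise_sd)
}

# Control-condition morphology parameters per channel. delta acts
# multiplicatively on the subset listed in delta_parameter_map(); delta = 0
# reproduces these values exactly.
control_baselines <- function() {
  list(
    nucleus = list(rel_size = 0.42, intensity = 0.60, edge_soft = 0.10),
    endoplasmic_reticulum = list(texture_amp = 0.30, grain = 1.3,
                                 frag_density = 0.012, frag_amp = 0.30,
                                 frag_len_rel = 0.35),
    rna_nucleolus = list(puncta_density = 0.018, puncta_amp = 0.50,
                         nucleolus_rel = 0.16, nucleolus_amp = 0.85,
                         base = 0.08),
    actin_membrane_golgi = list(ring_amp = 0.42, ring_rel_width = 0.06,
                                filament_density = 0.010, filament_amp = 0.35,
                                patch_amp = 0.40),
    mitochondria = list(density = 0.030, seg_len_rel = 0.25, amp = 0.40,
                        width = 0.8)
  )
}

#' Which morphology parameters each channel's effect size scales
#'
#' Effect size `delta` multiplies parameter `p` by `1 + w * delta` with the
#' listed weight `w`; all other parameters stay at their control baselines.
#'
#' @return Named list: channel -> named numeric vector of weights.
#' @export
delta_parameter_map <- function() {
  list(
    nucleus = c(rel_size = 0.35, intensity = 0.25),
    # ER stress phenotype: the continuous reticulum dims and fragments into
    # bright sheet remnants
    endoplasmic_reticulum = c(texture_amp = -0.45, grain = -0.50,
                              frag_density = 1.00, frag_amp = 0.50),
    rna_nucleolus = c(puncta_density = 1.00, nucleolus_rel = 0.40),
    actin_membrane_golgi = c(ring_amp = 0.40, ring_rel_width = 0.60,
                             filament_density = 1.00),
    mitochondria = c(density = 1.00, seg_len_rel = 0.30, amp = 0.15)
  )
}

# apply delta to baselines; negative weights shrink (floored at 25% of
# baseline so parameters stay positive)
perturbed_params <- function(delta) {
  base <- control_baselines()
  wmap <- delta_parameter_map()
  for (ch in names(base)) {
    d <- delta[[ch]]
    if (d > 0) {
      for (p in names(wmap[[ch]])) {
        f <- 1 + wmap[[ch]][[p]] * d
        base[[ch]][[p]] <- base[[ch]][[p]] * max(f, 0.25)
      }
    }
  }
  base
}

# within-cell mean intensity typical of each channel under control rendering;
# used by the "debris" outlier to invert the stain brightness pattern
stain_levels <- function() {
  c(nucleus = 0.60, endoplasmic_reticulum = 0.30, rna_nucleolus = 0.50,
    actin_membrane_golgi = 0.40, mitochondria = 0.45)
}

place_centroids <- function(n, size, margin, min_sep) {
  pts <- matrix(numeric(0), ncol = 2)
  lo <- margin + 1
  hi <- size - margin
  if (hi <= lo) {
    stop("field of size ", size, " cannot hold any cell with margin ", margin)
  }
  attempts <- 0L
  max_attempts <- 500L * n
  while (nrow(pts) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("unable to place ", n, " cells with minimum separation ",
           round(min_sep, 1), " px in a ", size, "x", size,
           " field (placed ", nrow(pts), "); reduce cells_per_field or ",
           "min_sep_factor, or enlarge the field")
    }
    cand <- stats::runif(2, lo, hi)
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep) {
      pts <- rbind(pts, cand)
    }
  }
  pts
}

# squared elliptical metric on a (2h+1)^2 window grid centred at (jr, jc)
ellipse_metric <- function(half, jr, jc, a, b, theta) {
  off <- seq(-half, half)
  dr <- matrix(off - jr, nrow = 2 * half + 1, ncol = 2 * half + 1)
  dc <- matrix(off - jc, nrow = 2 * half + 1, ncol = 2 * half + 1, byrow = TRUE)
  u <- (dc * cos(theta) + dr * sin(theta)) / a
  v <- (-dc * sin(theta) + dr * cos(theta)) / b
  u^2 + v^2
}

sample_mask_points <- function(idx, n, nrow_win) {
  if (!length(idx)) idx <- as.integer((nrow_win * nrow_win + 1) / 2)
  i <- idx[sample.int(length(idx), n, replace = TRUE)]
  cbind(row = (i - 1) %% nrow_win + 1, col = (i - 1) %/% nrow_win + 1)
}

# render one healthy cell into a (2*half+1)^2 x 5 window; returns the window
# and planted per-cell statistics
render_cell_window <- function(half, params, cell_radius) {
  R <- cell_radius
  wn <- 2L * half + 1L
  win <- array(0, c(wn, wn, n_channels()))
  theta <- stats::runif(1, 0, pi)
  # right-skewed (log-normal) cell size, as in real populations; this shared
  # covariance axis anchors the QC reference profile identically in every line
  s <- min(max(stats::rlnorm(1, 0, 0.18), 0.70), 1.25)
  a <- R * s * stats::runif(1, 0.85, 1.05)
  b <- R * s * stats::runif(1, 0.55, 0.78)

  d_cyto <- ellipse_metric(half, 0, 0, a, b, theta)
  cyto <- d_cyto <= 1
  cyto_area <- sum(cyto)

  np <- params$nucleus
  jr <- stats::runif(1, -0.12, 0.12) * R
  jc <- stats::runif(1, -0.12, 0.12) * R
  an <- np$rel_size * a
  bn <- np$rel_size * b
  d_nuc <- ellipse_metric(half, jr, jc, an, bn, theta)
  nuc_soft <- 1 / (1 + exp((sqrt(d_nuc) - 1) / np$edge_soft))
  win[, , 1] <- np$intensity * nuc_soft * (1 - 0.20 * pmin(d_nuc, 1))

  cyto_idx <- which(cyto)

  ep <- params$endoplasmic_reticulum
  z <- EBImage::gblur(matrix(stats::rnorm(wn * wn), wn, wn), sigma = ep$grain)
  z <- (z - min(z)) / (diff(range(z)) + 1e-12)
  ch2 <- ep$texture_amp * (0.35 + 0.9 * z)
  # ER sheet fragments: bright elongated patches (fragmentation shifts count)
  n_frag <- stats::rpois(1, ep$frag_density * cyto_area)
  if (n_frag > 0) {
    p <- sample_mask_points(cyto_idx, n_frag, wn)
    ch2 <- .stamp_primitives_cpp(ch2, p[, 1], p[, 2],
                                 stats::runif(n_frag, 0, pi),
                                 ep$frag_len_rel * R *
                                   stats::runif(n_frag, 0.7, 1.3),
                                 rep(1.3, n_frag),
                                 ep$frag_amp * stats::runif(n_frag, 0.8, 1.2))
  }
  win[, , 2] <- ch2 * cyto * (1 - 0.7 * nuc_soft)

  rp <- params$rna_nucleolus
  ch3 <- rp$base * cyto
  n_punc <- stats::rpois(1, rp$puncta_density * cyto_area)
  n_nucleoli <- sample(1:2, 1)
  pp <- sample_mask_points(cyto_idx, max(n_punc, 1L), wn)[seq_len(n_punc), ,
                                                          drop = FALSE]
  nuc_pos <- cbind(half + 1 + jr + stats::runif(n_nucleoli, -0.3, 0.3) * bn,
                   half + 1 + jc + stats::runif(n_nucleoli, -0.3, 0.3) * an)
  ch3 <- .stamp_primitives_cpp(
    ch3,
    c(pp[, 1], nuc_pos[, 1]), c(pp[, 2], nuc_pos[, 2]),
    numeric(n_punc + n_nucleoli), numeric(n_punc + n_nucleoli),
    c(rep(0.9, n_punc), rep(rp$nucleolus_rel * R, n_nucleoli)),
    c(rp$puncta_amp * stats::runif(n_punc, 0.7, 1.1),
      rep(rp$nucleolus_amp, n_nucleoli)))
  win[, , 3] <- ch3 * cyto

  ap <- params$actin_membrane_golgi
  rim <- exp(-(sqrt(d_cyto) - 0.93)^2 / (2 * ap$ring_rel_width^2))
  ch4 <- ap$ring_amp * rim
  n_fil <- stats::rpois(1, ap$filament_density * cyto_area)
  pf <- sample_mask_points(cyto_idx, max(n_fil, 1L), wn)[seq_len(n_fil), ,
                                                         drop = FALSE]
  patch_pos <- c(half + 1 + jr + 0.5 * bn * sign(stats::runif(1) - 0.5),
                 half + 1 + jc + 0.5 * an * sign(stats::runif(1) - 0.5))
  ch4 <- .stamp_primitives_cpp(
    ch4,
    c(pf[, 1], patch_pos[1]), c(pf[, 2], patch_pos[2]),
    c(theta + stats::runif(n_fil, -0.5, 0.5), 0),
    c(stats::runif(n_fil, 0.8, 1.6) * b, 0),
    c(rep(0.7, n_fil), 0.22 * R),
    c(rep(ap$filament_amp, n_fil), ap$patch_amp))
  win[, , 4] <- ch4 * (cyto | rim > 0.05)

  mp <- params$mitochondria
  cyto_only_idx <- which(cyto & d_nuc > 1)
  n_mito <- stats::rpois(1, mp$density * cyto_area)
  ch5 <- matrix(0, wn, wn)
  if (n_mito > 0) {
    p <- sample_mask_points(cyto_only_idx, n_mito, wn)
    ch5 <- .stamp_primitives_cpp(ch5, p[, 1], p[, 2],
                                 stats::runif(n_mito, 0, pi),
                                 mp$seg_len_rel * R *
                                   stats::runif(n_mito, 0.6, 1.4),
                                 rep(mp$width, n_mito),
                                 mp$amp * stats::runif(n_mito, 0.8, 1.2))
  }
  win[, , 5] <- ch5 * cyto

  list(win = win, a = a, b = b, theta = theta, mito_count = n_mito,
       puncta_count = n_punc)
}

# degenerate/outlier cell window
render_outlier_window <- function(half, kind, cell_radius) {
  R <- cell_radius
  wn <- 2L * half + 1L
  win <- array(0, c(wn, wn, n_channels()))
  theta <- stats::runif(1, 0, pi)
  a <- R * stats::runif(1, 0.75, 1.1)
  b <- R * stats::runif(1, 0.55, 0.95)
  d <- ellipse_metric(half, 0, 0, a, b, theta)
  blob <- d <= 1
  if (kind == "debris") {
    lv <- 0.85 - stain_levels()   # inverted stain brightness pattern
    for (ch in seq_len(n_channels())) {
      speck <- lv[[ch]] + stats::runif(wn * wn, -0.30, 0.30)
      win[, , ch] <- pmax(matrix(speck, wn, wn), 0) * blob
    }
  } else if (kind == "saturated") {
    soft <- 1 / (1 + exp((sqrt(d) - 1) / 0.05))
    for (ch in seq_len(n_channels())) win[, , ch] <- soft
  } else { # empty
    win[, , 1] <- 0.16 * (d <= 0.25)
    for (ch in 2:n_channels()) win[, , ch] <- 0.03 * blob
  }
  list(win = win, a = a, b = b, theta = theta,
       mito_count = NA_integer_, puncta_count = NA_integer_)
}

#' Render one synthetic five-channel field
#'
#' Places non-overlapping cells at random and renders each channel with
#' parametric 2-D primitives: the nucleus as a smooth ellipse, the ER as
#' band-limited texture around the nucleus, cytoplasmic RNA as puncta plus
#' nucleolar blobs, the actin/membrane/Golgi channel as a boundary ring,
#' filament strokes and a perinuclear patch, and mitochondria as elongated
#' puncta. Channel morphology parameters are shifted from control baselines by
#' the line's per-channel effect sizes; an `outlier_fraction` of cells is
#' rendered with corrupted morphology. Per-well multiplicative gain and
#' per-batch additive background are applied to all channels.
#'
#' @param spec A [perturbation_spec()].
#' @param nuisance List with `gain` (multiplicative, per well) and
#'   `background` (additive, per batch).
#' @param seed Integer seed; rendering is bit-reproducible for fixed
#'   `(spec, nuisance, seed, geom)`.
#' @param geom A [field_geometry()].
#' @param plate,well,site Provenance strings/index attached to the field.
#' @return A `FieldImage`: list with `pixels` (H x W x 5 array, intensities in
#'   \[0,1\]), provenance fields, and `truth` — a data.frame of planted cells
#'   (centroid `row`/`col`, `outlier` flag, semi-axes, mitochondrial punctum
#'   count).
#' @export
render_field <- function(spec, nuisance = list(gain = 1, background = 0.02),
                         seed, geom = field_geometry(),
                         plate = "P1", well = "A01", site = 1L) {
  stopifnot(inherits(spec, "PerturbationSpec"))
  set.seed(as.integer(seed))
  size <- geom$field_size
  R <- geom$cell_radius
  n <- if (length(geom$cells_per_field) == 1L) geom$cells_per_field else
    sample(geom$cells_per_field[1]:geom$cells_per_field[2], 1L)
  half <- as.integer(ceiling(1.45 * R))
  margin <- half + 1L
  pts <- place_centroids(n, size, margin, geom$min_sep_factor * R)
  outlier <- stats::runif(n) < spec$outlier_fraction
  params <- perturbed_params(spec$delta)

  pixels <- array(0, c(size, size, n_channels()))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cw <- if (outlier[i]) {
      render_outlier_window(half, spec$outlier_kind, R)
    } else {
      render_cell_window(half, params, R)
    }
    r0 <- round(pts[i, 1]) - half
    c0 <- round(pts[i, 2]) - half
    rows <- r0:(r0 + 2L * half)
    cols <- c0:(c0 + 2L * half)
    pixels[rows, cols, ] <- pixels[rows, cols, ] + cw$win
    truth[[i]] <- data.frame(
      plate = plate, well = well, site = as.integer(site),
      line_id = spec$line_id, cell_index = i,
      row = pts[i, 1], col = pts[i, 2],
      outlier = outlier[i],
      semi_a = cw$a, semi_b = cw$b,
      mito_count = cw$mito_count,
      stringsAsFactors = FALSE
    )
  }
  # detector-style gain: scales the whole optical signal (stain + background
  # + read noise), so per-image standardization removes it entirely and well
  # identity carries no label information
  pixels <- pixels + nuisance$background +
    array(stats::rnorm(length(pixels), 0, geom$noise_sd), dim(pixels))
  pixels <- pixels * nuisance$gain
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1
  structure(
    list(pixels = pixels, plate = plate, well = well, site = as.integer(site),
         line_id = spec$line_id, truth = do.call(rbind, truth)),
    class = "FieldImage"
  )
}

#' Screen simulation manifest
#'
#' Defines an arrayed synthetic screen: one or more cell lines (at least one
#' control with all-zero effects is conventional), the plate layout
#' (wells per line, sites per well), rendering geometry, nuisance-variation
#' magnitudes and a master seed from which every stream seed is derived.
#'
#' @param lines List of [perturbation_spec()] objects; `line_id`s must be
#'   unique.
#' @param wells_per_line,sites_per_well Plate layout counts.
#' @param seed Master integer seed; generation is bit-reproducible.
#' @param geom A [field_geometry()].
#' @param gain_sd SD of the per-well log-normal multiplicative gain
#'   (`meanlog = 0`).
#' @param background_mean,background_cv Mean and coefficient of variation of
#'   the per-plate (batch) additive background level.
#' @return A `SimManifest` object.
#' @export
sim_manifest <- function(lines, wells_per_line = 2L, sites_per_well = 3L,
                         seed = 1L, geom = field_geometry(),
                         gain_sd = 0.10, background_mean = 0.02,
                         background_cv = 0.25) {
  stopifnot(is.list(lines), length(lines) >= 1L,
            all(vapply(lines, inherits, logical(1), "PerturbationSpec")))
  ids <- vapply(lines, `[[`, character(1), "line_id")
  if (anyDuplicated(ids)) {
    stop("duplicate line_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(
    list(lines = lines, line_ids = ids,
         wells_per_line = as.integer(wells_per_line),
         sites_per_well = as.integer(sites_per_well),
         seed = as.integer(seed), geom = geom, gain_sd = gain_sd,
         background_mean = background_mean, background_cv = background_cv),
    class = "SimManifest"
  )
}

well_name <- function(i) {
  sprintf("%s%02d", LETTERS[((i - 1L) %/% 12L) %% 8L + 1L], (i - 1L) %% 12L + 1L)
}

#' Enumerate the fields a manifest will generate
#'
#' One row per (line, well, site) with the derived rendering seed and the
#' well/batch nuisance parameters. [simulate_screen()] renders exactly this
#' plan; pipelines that cannot hold all fields in memory can iterate it and
#' call [render_field()] row by row.
#'
#' @param manifest A [sim_manifest()].
#' @return data.frame with columns line_id, plate, well, site, seed, gain,
#'   background.
#' @export
field_plan <- function(manifest) {
  stopifnot(inherits(manifest, "SimManifest"))
  n_lines <- length(manifest$lines)
  n_wells <- n_lines * manifest$wells_per_line
  well_idx <- seq_len(n_wells)
  plate_idx <- (well_idx - 1L) %/% 96L + 1L
  set.seed(mix_seed(manifest$seed, 1001))
  gains <- stats::rlnorm(n_wells, meanlog = 0, sdlog = manifest$gain_sd)
  set.seed(mix_seed(manifest$seed, 1002))
  n_plates <- max(plate_idx)
  bg <- pmax(stats::rnorm(n_plates, manifest$background_mean,
                          manifest$background_cv * manifest$background_mean), 0)
  rows <- list()
  w <- 0L
  for (li in seq_len(n_lines)) {
    for (wi in seq_len(manifest$wells_per_line)) {
      w <- w + 1L
      for (si in seq_len(manifest$sites_per_well)) {
        rows[[length(rows) + 1L]] <- data.frame(
          line_id = manifest$line_ids[li],
          plate = sprintf("P%d", plate_idx[w]),
          well = well_name(w),
          site = si,
          seed = mix_seed(manifest$seed, li, wi, si),
          gain = gains[w],
          background = bg[plate_idx[w]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a full synthetic screen
#'
#' Renders every field in the manifest's [field_plan()] and assembles the
#' ground-truth tables used by downstream recovery tests.
#'
#' @param manifest A [sim_manifest()].
#' @return A `ScreenSim` list: `fields` (list of `FieldImage`), `cells`
#'   (per-planted-cell ground truth), `lines` (per-line truth: planted effect
#'   sizes, target channel, cell/outlier counts) and `plan`.
#' @export
simulate_screen <- function(manifest) {
  plan <- field_plan(manifest)
  spec_by_id <- stats::setNames(manifest$lines, manifest$line_ids)
  fields <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    fields[[i]] <- render_field(
      spec_by_id[[p$line_id]],
      nuisance = list(gain = p$gain, background = p$background),
      seed = p$seed, geom = manifest$geom,
      plate = p$plate, well = p$well, site = p$site
    )
  }
  cells <- do.call(rbind, lapply(fields, `[[`, "truth"))
  lines <- do.call(rbind, lapply(manifest$lines, function(sp) {
    n_cells <- sum(cells$line_id == sp$line_id)
    n_out <- sum(cells$line_id == sp$line_id & cells$outlier)
    df <- data.frame(line_id = sp$line_id,
                     target_channel = sp$target_channel,
                     outlier_fraction = sp$outlier_fraction,
                     n_cells = n_cells, n_outliers = n_out,
                     stringsAsFactors = FALSE)
    for (ch in channel_names()) df[[paste0("delta_", ch)]] <- sp$delta[[ch]]
    df
  }))
  structure(list(fields = fields, cells = cells, lines = lines, plan = plan,
                 manifest = manifest),
            class = "ScreenSim")
}
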