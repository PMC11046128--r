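#' Write a simulated screen to disk
#'
#' One 16-bit grayscale TIFF per channel per field, named
#' `{plate}_{well}_{site}_{channel}.tiff`, plus the ground-truth cell table
#' (`ground_truth.csv`), the per-line truth (`lines.csv`) and the manifest
#' parameters (`manifest.yaml`).
#'
#' @param sim A `ScreenSim` from [simulate_screen()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_screen_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "ScreenSim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (fl in sim$fields) write_field_tiffs(fl, dir)
  utils::write.csv(sim$cells, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$lines, file.path(dir, "lines.csv"), row.names = FALSE)
  m <- sim$manifest
  yaml::write_yaml(list(
    lines = lapply(m$lines, function(sp) list(
      line_id = sp$line_id, effects = as.list(sp$delta),
      outlier_fraction = sp$outlier_fraction,
      outlier_kind = sp$outlier_kind)),
    wells_per_line = m$wells_per_line, sites_per_well = m$sites_per_well,
    seed = m$seed, geom = m$geom, gain_sd = m$gain_sd,
    background_mean = m$background_mean, background_cv = m$background_cv),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_screen_sim
#' @param field A `FieldImage`.
#' @export
write_field_tiffs <- function(field, dir) {
  stopifnot(inherits(field, "FieldImage"))
  for (ch in seq_len(n_channels())) {
    path <- file.path(dir, sprintf("%s_%s_%d_%s.tiff", field$plate,
                                   field$well, field$site,
                                   channel_names()[ch]))
    tiff::writeTIFF(field$pixels[, , ch], path, bits.per.sample = 16L)
  }
  invisible(dir)
}

#' Read one field back from per-channel TIFFs
#'
#' @param dir Directory written by [write_screen_sim()].
#' @param plate,well,site Field identity.
#' @param line_id Optional line annotation to attach.
#' @return A `FieldImage` (without ground truth).
#' @export
read_field_tiffs <- function(dir, plate, well, site, line_id = NA_character_) {
  pixels <- NULL
  for (ch in seq_len(n_channels())) {
    path <- file.path(dir, sprintf("%s_%s_%d_%s.tiff", plate, well, site,
                                   channel_names()[ch]))
    m <- tiff::readTIFF(path)
    if (is.null(pixels)) pixels <- array(0, c(dim(m), n_channels()))
    pixels[, , ch] <- m
  }
  structure(list(pixels = pixels, plate = plate, well = well,
                 site = as.integer(site), line_id = line_id, truth = NULL),
            class = "FieldImage")
}

#' Write dataset membership manifests
#'
#' @param dataset A `ScreenDataset`.
#' @param path CSV path.
#' @return Invisibly, the path.
#' @export
write_dataset_manifest <- function(dataset, path) {
  stopifnot(inherits(dataset, "ScreenDataset"))
  df <- dataset$members
  df$gene_id <- dataset$gene_id
  df$channel <- dataset$channel
  df$replicate_seed <- dataset$replicate_seed
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write AUC records and QC summaries
#'
#' @param records AUC record data.frame.
#' @param path CSV path.
#' @return Invisibly, the path.
#' @export
write_auc_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
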