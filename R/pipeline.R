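#' Pipeline configuration
#'
#' Collects the tunable settings of the image-to-AUC pipeline in one place.
#' The defaults are the scaled-down synthetic-benchmark regime (32-px crops,
#' a few hundred images per side, a handful of epochs with a matched higher
#' learning rate) which runs a full screen on one CPU in minutes; the
#' full-scale screen regime is `target = 3000`, `replicates = 5`,
#' `epochs = 100`, `learning_rate = 1e-4`, `crop_side = 96`.
#'
#' @param crop_side Square crop side in pixels (divisible by 4).
#' @param target Target images per side of each comparison.
#' @param replicates Replicate datasets (and classifiers) per gene x channel.
#' @param channels Channels to train on (default all five).
#' @param epochs,learning_rate,batch_size,widths Classifier settings
#'   ([train_config()]).
#' @param fractions Train/validation/test fractions.
#' @param cutoff,qc_reference,qc_standardize Spearman filter settings
#'   ([spearman_filter()]).
#' @param min_cells Minimum post-QC cells per line to proceed.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(crop_side = 32L, target = 400L, replicates = 3L,
                            channels = channel_names(), epochs = 8L,
                            learning_rate = 1e-3, batch_size = 32L,
                            widths = c(8L, 16L), fractions = c(0.8, 0.1, 0.1),
                            cutoff = 0.15, qc_reference = "pooled-median",
                            qc_standardize = TRUE, min_cells = 20L) {
  structure(list(crop_side = as.integer(crop_side), target = as.integer(target),
                 replicates = as.integer(replicates), channels = channels,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 widths = as.integer(widths), fractions = fractions,
                 cutoff = cutoff, qc_reference = qc_reference,
                 qc_standardize = qc_standardize,
                 min_cells = as.integer(min_cells)),
            class = "PipelineConfig")
}

#' Segment, crop and QC-filter a whole simulated screen
#'
#' Streams over the manifest's [field_plan()] (fields are rendered, processed
#' and discarded one at a time), crops passing cells, extracts features and
#' applies the Spearman filter.
#'
#' @param manifest A [sim_manifest()].
#' @param config A [pipeline_config()].
#' @return List with `crop_store` (named list of retained `CellCrop`s),
#'   `retained_ids` (list line_id -> cell ids), `features`, `qc`
#'   (filter output), `flags` (crop-level quality flags) and `truth_cells`.
#' @export
collect_screen_cells <- function(manifest, config = pipeline_config()) {
  plan <- field_plan(manifest)
  spec_by_id <- stats::setNames(manifest$lines, manifest$line_ids)
  sparams <- segment_params(cell_radius = manifest$geom$cell_radius)
  crops <- list()
  flags <- list()
  truth <- list()
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    fl <- render_field(spec_by_id[[p$line_id]],
                       nuisance = list(gain = p$gain, background = p$background),
                       seed = p$seed, geom = manifest$geom,
                       plate = p$plate, well = p$well, site = p$site)
    masks <- segment_field(fl, sparams)
    cc <- crop_cells(fl, masks, side = config$crop_side, params = sparams)
    crops <- c(crops, cc$crops)
    flags[[i]] <- cc$flags
    truth[[i]] <- fl$truth
  }
  features <- feature_table(crops)
  ctrl <- if (config$qc_reference == "control") control_line_of(manifest)
          else NULL
  qc <- spearman_filter(features, cutoff = config$cutoff,
                        reference = config$qc_reference,
                        standardize = config$qc_standardize,
                        control_line = ctrl)
  keep <- qc$results$cell_id[qc$results$retained]
  crop_store <- stats::setNames(crops, vapply(crops, `[[`, character(1),
                                              "cell_id"))
  crop_store <- crop_store[keep]
  retained_ids <- split(keep, qc$results$line_id[qc$results$retained])
  list(crop_store = crop_store, retained_ids = retained_ids,
       features = features, qc = qc,
       flags = do.call(rbind, flags), truth_cells = do.call(rbind, truth))
}

control_line_of <- function(manifest) {
  for (sp in manifest$lines) {
    if (all(sp$delta == 0)) return(sp$line_id)
  }
  stop("manifest has no control line (all-zero effects)")
}

#' Run the full image-to-AUC screen pipeline
#'
#' simulate -> segment -> crop -> features -> Spearman QC -> balanced
#' augmented datasets -> per gene x channel x replicate CNN training ->
#' test AUC records. The control side of every comparison is drawn with a
#' replicate-level screen-wide seed, so within a replicate the same control
#' images are used for every knockout gene.
#'
#' @param manifest A [sim_manifest()]; must contain a control line with
#'   all-zero effects.
#' @param config A [pipeline_config()].
#' @param cells Optional precomputed result of [collect_screen_cells()].
#' @return List with `records` (AUC record data.frame), `summaries` (list of
#'   `GeneSummary` per knockout gene), `qc_summary`, `lines` (planted ground
#'   truth) and `cells` (the collected cell set).
#' @export
run_screen_pipeline <- function(manifest, config = pipeline_config(),
                                cells = NULL) {
  if (is.null(cells)) cells <- collect_screen_cells(manifest, config)
  control <- control_line_of(manifest)
  control_ids <- cells$retained_ids[[control]]
  if (length(control_ids) < config$min_cells) {
    stop("only ", length(control_ids), " control cells survived QC (need >= ",
         config$min_cells, ")")
  }
  genes <- setdiff(manifest$line_ids, control)
  records <- list()
  for (gi in seq_along(genes)) {
    gene <- genes[gi]
    ko_ids <- cells$retained_ids[[gene]]
    if (is.null(ko_ids) || length(ko_ids) < config$min_cells) {
      stop("only ", length(ko_ids), " cells survived QC for line ", gene)
    }
    for (ci in seq_along(config$channels)) {
      ch <- config$channels[ci]
      for (r in seq_len(config$replicates)) {
        rep_seed <- mix_seed(manifest$seed, 500L, gi, channel_slot(ch), r)
        ctrl_seed <- mix_seed(manifest$seed, 77L, r)
        members <- build_group(ko_ids, control_ids, target = config$target,
                               seed = rep_seed, control_seed = ctrl_seed)
        ds <- split_dataset(members, fractions = config$fractions,
                            seed = rep_seed, gene_id = gene, channel = ch)
        tr <- materialize_split(ds, cells$crop_store, "train")
        va <- materialize_split(ds, cells$crop_store, "val")
        te <- materialize_split(ds, cells$crop_store, "test")
        cfg <- train_config(epochs = config$epochs,
                            learning_rate = config$learning_rate,
                            batch_size = config$batch_size, seed = rep_seed,
                            widths = config$widths)
        model <- train_classifier(tr, va, cfg)
        ev <- evaluate_auc(model, te)
        records[[length(records) + 1L]] <- auc_record(
          gene, ch, rep_seed, ev$auc, ev$n_test_pos, ev$n_test_neg)
      }
    }
  }
  records <- do.call(rbind, records)
  summaries <- lapply(genes, function(g)
    aggregate_gene(records[records$gene_id == g, , drop = FALSE]))
  names(summaries) <- genes
  list(records = records, summaries = summaries,
       qc_summary = cells$qc$summary,
       lines = NULL, cells = cells)
}
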