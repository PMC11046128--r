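#' Construct an AUC record
#'
#' One row of the screen-wide result table: the test AUC of one gene x
#' channel x replicate classifier.
#'
#' @param gene_id,channel,replicate_seed Identity of the comparison.
#' @param auc Test AUC in \[0,1\].
#' @param n_test_pos,n_test_neg Test-set counts per class.
#' @return One-row data.frame.
#' @export
auc_record <- function(gene_id, channel, replicate_seed, auc,
                       n_test_pos = NA_integer_, n_test_neg = NA_integer_) {
  stopifnot(auc >= 0, auc <= 1)
  data.frame(gene_id = gene_id, channel = channel,
             replicate_seed = as.integer(replicate_seed), auc = auc,
             n_test_pos = n_test_pos, n_test_neg = n_test_neg,
             stringsAsFactors = FALSE)
}

#' Aggregate AUC records into a per-gene summary
#'
#' The gene's overall morphological-variation score is the mean AUC over all
#' channel x replicate records (25 in the full design: 5 channels x 5
#' replicates), with the sample SD over the same records; per-channel means
#' over replicates support organelle attribution.
#'
#' @param records data.frame of AUC records for one gene.
#' @return A `GeneSummary` list: `gene_id`, `mean_auc`, `sd_auc`,
#'   `per_channel_mean_auc` (named, fixed channel order), `top_channel`,
#'   `n_records`, `complete` (TRUE when channels x replicates are all
#'   present).
#' @export
aggregate_gene <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  gene <- unique(records$gene_id)
  if (length(gene) != 1L) stop("records must share one gene_id")
  if (anyDuplicated(records[, c("channel", "replicate_seed")])) {
    stop("duplicate (channel, replicate) record for gene ", gene)
  }
  per_channel <- vapply(channel_names(), function(ch) {
    v <- records$auc[records$channel == ch]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  pc <- per_channel[!is.na(per_channel)]
  top <- if (length(pc)) names(pc)[which.max(pc)] else NA_character_
  n_rep <- length(unique(records$replicate_seed))
  structure(
    list(gene_id = gene,
         mean_auc = mean(records$auc),
         sd_auc = if (nrow(records) > 1) stats::sd(records$auc) else 0,
         per_channel_mean_auc = per_channel,
         top_channel = top,
         n_records = nrow(records),
         complete = nrow(records) == n_channels() * n_rep &&
           all(!is.na(per_channel))),
    class = "GeneSummary"
  )
}

#' Attribute a gene's morphological effect to an organelle channel
#'
#' The channel with the maximal per-channel mean AUC; exact ties are broken
#' by the fixed channel order ([channel_specs()]) and flagged.
#'
#' @param summary A `GeneSummary` with all five per-channel means present.
#' @return List with `top_channel`, `margin` (gap to the runner-up) and `tie`.
#' @export
attribute_organelle <- function(summary) {
  stopifnot(inherits(summary, "GeneSummary"))
  pc <- summary$per_channel_mean_auc[channel_names()]
  if (any(is.na(pc))) {
    stop("missing per-channel mean for: ",
         paste(names(pc)[is.na(pc)], collapse = ", "))
  }
  best <- which.max(pc)   # first maximum in fixed channel order
  sorted <- sort(pc, decreasing = TRUE)
  list(top_channel = names(pc)[best],
       margin = unname(sorted[1] - sorted[2]),
       tie = sum(pc == pc[best]) > 1L)
}

#' Compare two genes at a shared locus
#'
#' Welch's unequal-variance two-sample t test on the per-(channel, replicate)
#' AUC values of the two genes; the higher-mean gene is prioritized as the
#' likelier pathological candidate iff p < alpha. Degenerate inputs (zero
#' variance in both groups) are resolved exactly: p = 1 for equal means,
#' p = 0 otherwise.
#'
#' @param records_a,records_b AUC record data.frames for the two genes (>= 2
#'   records each).
#' @param alpha Significance level for prioritization (default 0.05).
#' @param locus_id Optional locus label carried into the result.
#' @return A `LocusComparison` one-row data.frame: `locus_id`, `gene_a`,
#'   `gene_b`, `mean_a`, `mean_b`, `delta_mean_auc`, `p_value`,
#'   `prioritized_gene` (NA when not significant).
#' @export
compare_locus_genes <- function(records_a, records_b, alpha = 0.05,
                                locus_id = NA_character_) {
  a <- records_a$auc
  b <- records_b$auc
  if (length(a) < 2L || length(b) < 2L) {
    stop("each gene needs at least 2 AUC records")
  }
  gene_a <- unique(records_a$gene_id)
  gene_b <- unique(records_b$gene_id)
  stopifnot(length(gene_a) == 1L, length(gene_b) == 1L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
  } else {
    p <- stats::t.test(a, b, var.equal = FALSE)$p.value
  }
  delta <- mean(a) - mean(b)
  prioritized <- if (p < alpha && delta != 0) {
    if (delta > 0) gene_a else gene_b
  } else NA_character_
  data.frame(locus_id = locus_id, gene_a = gene_a, gene_b = gene_b,
             mean_a = mean(a), mean_b = mean(b), delta_mean_auc = delta,
             p_value = p, prioritized_gene = prioritized,
             stringsAsFactors = FALSE)
}

#' Write the screen report
#'
#' Deterministic CSV/JSON rendering of a finished screen: the per-gene
#' ranking by mean AUC, the gene x channel AUC matrix and the locus
#' comparison table.
#'
#' @param summaries List of `GeneSummary` objects.
#' @param comparisons Optional data.frame of locus comparisons.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the list of file paths written.
#' @export
write_screen_report <- function(summaries, comparisons = NULL, dir) {
  stopifnot(length(summaries) >= 1L,
            all(vapply(summaries, inherits, logical(1), "GeneSummary")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ranking <- data.frame(
    gene_id = vapply(summaries, `[[`, character(1), "gene_id"),
    mean_auc = vapply(summaries, `[[`, numeric(1), "mean_auc"),
    sd_auc = vapply(summaries, `[[`, numeric(1), "sd_auc"),
    top_channel = vapply(summaries, `[[`, character(1), "top_channel"),
    n_records = vapply(summaries, `[[`, integer(1), "n_records"),
    complete = vapply(summaries, `[[`, logical(1), "complete"),
    stringsAsFactors = FALSE
  )
  ranking <- ranking[order(-ranking$mean_auc, ranking$gene_id), ]
  mat <- do.call(rbind, lapply(summaries, function(s)
    s$per_channel_mean_auc[channel_names()]))
  matrix_df <- cbind(data.frame(gene_id = ranking$gene_id[
    match(vapply(summaries, `[[`, character(1), "gene_id"), ranking$gene_id)],
    stringsAsFactors = FALSE), as.data.frame(mat))
  paths <- list(
    ranking = file.path(dir, "gene_ranking.csv"),
    matrix = file.path(dir, "gene_channel_auc.csv"),
    report = file.path(dir, "screen_report.json")
  )
  utils::write.csv(ranking, paths$ranking, row.names = FALSE)
  utils::write.csv(matrix_df, paths$matrix, row.names = FALSE)
  report <- list(genes = ranking,
                 channel_fractions = as.list(
                   table(factor(ranking$top_channel,
                                levels = channel_names())) / nrow(ranking)))
  if (!is.null(comparisons)) {
    paths$loci <- file.path(dir, "locus_comparisons.csv")
    utils::write.csv(comparisons, paths$loci, row.names = FALSE)
    report$loci <- comparisons
  }
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(paths)
}
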