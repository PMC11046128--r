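#' Line reference feature profile
#'
#' The comparator against which each cell is scored: the element-wise median
#' feature vector over the line's cells.
#'
#' @param features Feature table ([feature_table()]): `cell_id`, `line_id` and
#'   one numeric column per feature.
#' @param line_id Line whose reference to compute.
#' @return Named numeric vector over the table's feature columns.
#' @export
line_reference_profile <- function(features, line_id) {
  rows <- features[features$line_id == line_id, feature_columns(features),
                   drop = FALSE]
  if (nrow(rows) == 0) stop("no cells for line '", line_id, "'")
  vapply(rows, stats::median, numeric(1))
}

feature_columns <- function(features) {
  setdiff(names(features),
          c("cell_id", "line_id", "truth_outlier", "rho", "retained"))
}

# frozen per-group transform + reference profile; reapplying with the same
# object reproduces the pre-filter scoring exactly
qc_reference_set <- function(mat, line_ids, reference, standardize,
                             control_line = NULL) {
  groups <- switch(reference,
    "global" = list(`__shared__` = seq_len(nrow(mat))),
    "pooled-median" = split(seq_len(nrow(mat)), line_ids),
    "control" = {
      if (is.null(control_line)) {
        stop("reference = \"control\" needs a control_line")
      }
      idx <- which(line_ids == control_line)
      if (!length(idx)) stop("no cells for control line '", control_line, "'")
      list(`__shared__` = idx)
    },
    split(seq_len(nrow(mat)), line_ids)
  )
  refs <- lapply(groups, function(idx) {
    sub <- mat[idx, , drop = FALSE]
    if (standardize) {
      center <- colMeans(sub)
      scale <- apply(sub, 2, stats::sd)
      scale[!is.finite(scale) | scale == 0] <- 1
      sub <- sweep(sweep(sub, 2, center, "-"), 2, scale, "/")
    } else {
      center <- rep(0, ncol(sub))
      scale <- rep(1, ncol(sub))
    }
    list(center = center, scale = scale,
         profile = apply(sub, 2, stats::median))
  })
  if (reference == "pooled-median") {
    # per-line standardization, but one screen-shared profile: the pooled
    # median of the per-line standardized table. The retention rule is then
    # the same function of a cell's within-line deviation profile in every
    # line, so filtering cannot manufacture line differences.
    z <- mat
    for (l in names(refs)) {
      idx <- groups[[l]]
      z[idx, ] <- sweep(sweep(mat[idx, , drop = FALSE], 2,
                              refs[[l]]$center, "-"),
                        2, refs[[l]]$scale, "/")
    }
    shared <- apply(z, 2, stats::median)
    for (l in names(refs)) refs[[l]]$profile <- shared
  }
  structure(list(reference = reference, standardize = standardize,
                 refs = refs), class = "QCReferenceSet")
}

#' Spearman-correlation cell filter
#'
#' Scores every cell by the Spearman rank correlation (midranks for ties)
#' between its feature vector and a frozen reference profile — the
#' element-wise median vector of its line (or of the whole screen) — and
#' removes non-correlated cells below the cutoff. This is the screen's
#' mechanism for discarding artifact cells and damping well-to-well and
#' batch-to-batch variation.
#'
#' By default each feature column is standardized (z-scored) within the
#' reference group before correlating. Raw morphological features span many
#' orders of magnitude (mask area and integrated intensities always rank above
#' the unit-interval intensity statistics, for any cell whatsoever), which
#' puts a high floor under the cross-feature rank correlation and makes a
#' fixed cutoff inoperative; on standardized columns the reference profile
#' captures the line's consensus deviation pattern and corrupted cells
#' genuinely decorrelate. Set `standardize = FALSE` for the raw-scale variant.
#'
#' References (and standardization parameters) are computed once from the
#' pre-filter table and returned; passing them back via `refs` re-applies the
#' frozen scoring, which makes the filter idempotent. Cells whose feature
#' vector has zero rank variance get an undefined correlation and are removed
#' with `rho_undefined` set, never silently scored.
#'
#' @param features Feature table ([feature_table()]).
#' @param cutoff Retention threshold in \[-1, 1\]; retained iff
#'   `rho >= cutoff`. Default 0.15.
#' @param reference `"line-median"` (per-line reference), `"pooled-median"`
#'   (per-line standardization with one screen-shared profile — the retention
#'   rule is identical for every line, which keeps filtering from
#'   manufacturing line differences; the pipeline default), `"global"` (one
#'   screen-wide reference) or `"control"` (reference and standardization
#'   anchored to the `control_line` cells and applied screen-wide).
#' @param standardize Standardize feature columns within the reference group
#'   before correlating (default TRUE).
#' @param control_line Line id supplying the reference when
#'   `reference = "control"`.
#' @param refs A `QCReferenceSet` from a previous run to freeze the scoring;
#'   NULL computes references from `features`.
#' @return List with `results` (one `QCResult` row per input cell: `cell_id`,
#'   `line_id`, `rho`, `rho_undefined`, `retained`), `summary` (one
#'   `RetentionSummary` row per line: `n_before`, `n_after`,
#'   `fraction_removed`) and `refs` (the frozen `QCReferenceSet`).
#' @export
spearman_filter <- function(features, cutoff = 0.15,
                            reference = c("line-median", "pooled-median",
                                          "global", "control"),
                            standardize = TRUE, refs = NULL,
                            control_line = NULL) {
  reference <- match.arg(reference)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L,
            cutoff >= -1, cutoff <= 1)
  fcols <- feature_columns(features)
  if (!length(fcols)) stop("feature table has no feature columns")
  mat <- as.matrix(features[, fcols, drop = FALSE])
  if (any(!is.finite(mat))) stop("feature table contains non-finite entries")
  if (is.null(refs)) {
    refs <- qc_reference_set(mat, features$line_id, reference, standardize,
                             control_line)
  } else {
    stopifnot(inherits(refs, "QCReferenceSet"))
  }
  n <- nrow(mat)
  rho <- rep(NA_real_, n)
  undef <- logical(n)
  for (i in seq_len(n)) {
    key <- if (refs$reference %in% c("global", "control")) "__shared__" else
      features$line_id[i]
    rf <- refs$refs[[key]]
    if (is.null(rf)) stop("no frozen reference for line '", key, "'")
    x <- (mat[i, ] - rf$center) / rf$scale
    r <- rf$profile
    if (stats::sd(x) == 0 || stats::sd(r) == 0) {
      undef[i] <- TRUE
    } else {
      rho[i] <- stats::cor(x, r, method = "spearman")
      if (is.na(rho[i])) undef[i] <- TRUE
    }
  }
  retained <- !undef & !is.na(rho) & rho >= cutoff
  results <- data.frame(
    cell_id = features$cell_id, line_id = features$line_id,
    rho = rho, rho_undefined = undef, retained = retained,
    stringsAsFactors = FALSE
  )
  lines <- unique(features$line_id)
  summary <- do.call(rbind, lapply(lines, function(l) {
    sel <- results$line_id == l
    nb <- sum(sel)
    na <- sum(results$retained[sel])
    data.frame(line_id = l, n_before = nb, n_after = na,
               fraction_removed = 1 - na / nb, stringsAsFactors = FALSE)
  }))
  list(results = results, summary = summary, refs = refs)
}
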