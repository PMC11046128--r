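#' Benchmark scenario definitions
#'
#' Seeded, laptop-sized synthetic screens that exercise the whole pipeline
#' and produce the package's calibration and recovery evidence:
#' \describe{
#'   \item{null}{a zero-effect knockout line vs control; classifiers should
#'     sit at chance (AUC about 0.5) across replicate seeds.}
#'   \item{graded}{mitochondrial effect sizes 0 / 0.5 / 1.5; mean AUC should
#'     increase strictly with the planted effect.}
#'   \item{attribution}{ten genes with a strong effect planted in a known
#'     channel each; the attributed organelle should match the planted one.}
#'   \item{locus}{two-gene loci with one strong-effect and one null gene;
#'     the strong gene should be prioritized.}
#'   \item{qc}{a line with 30 percent planted outlier cells; the Spearman
#'     filter should remove them.}
#' }
#' All scenarios use 256-px fields of ~18 cells (radius 13 px) and 32-px
#' crops; geometry, group sizes and training settings are stated in the
#' methods vignette.
#'
#' @param name Scenario name.
#' @param seed Master seed.
#' @return A `BenchmarkScenario` list with `name`, `manifest`, `config` and
#'   `expect` (the scenario's expectation descriptors).
#' @export
benchmark_scenario <- function(name = c("null", "graded", "attribution",
                                        "locus", "qc"), seed = 1L) {
  name <- match.arg(name)
  geom <- field_geometry(field_size = 272, cell_radius = 13,
                         cells_per_field = 18L, noise_sd = 0.008)
  mk <- function(lines, wells, sites, cfg) {
    list(manifest = sim_manifest(lines, wells_per_line = wells,
                                 sites_per_well = sites, seed = seed,
                                 geom = geom),
         config = cfg)
  }
  sc <- switch(
    name,
    null = mk(
      list(perturbation_spec("nontargeting_1", outlier_fraction = 0.02),
           perturbation_spec("KO_null", outlier_fraction = 0.02)),
      wells = 9L, sites = 25L,
      pipeline_config(target = 1500L, replicates = 10L,
                      channels = "mitochondria", epochs = 5L)),
    graded = mk(
      c(list(perturbation_spec("nontargeting_1", outlier_fraction = 0.02)),
        lapply(c(0, 0.5, 1.5), function(d)
          perturbation_spec(sprintf("KO_mito_%03d", round(100 * d)),
                            effects = c(mitochondria = d),
                            outlier_fraction = 0.02))),
      wells = 4L, sites = 14L,
      pipeline_config(target = 400L, replicates = 3L,
                      channels = "mitochondria", epochs = 8L)),
    attribution = mk(
      c(list(perturbation_spec("nontargeting_1", outlier_fraction = 0.02)),
        lapply(seq_len(10L), function(i) {
          ch <- channel_names()[(i - 1L) %% 5L + 1L]
          perturbation_spec(sprintf("KO_%02d_%s", i, ch),
                            effects = stats::setNames(1.2, ch),
                            outlier_fraction = 0.02)
        })),
      wells = 3L, sites = 8L,
      pipeline_config(target = 200L, replicates = 1L, epochs = 8L)),
    locus = mk(
      list(perturbation_spec("nontargeting_1", outlier_fraction = 0.02),
           perturbation_spec("gene_strong",
                             effects = stats::setNames(rep(1.3, 5),
                                                       channel_names()),
                             outlier_fraction = 0.02),
           perturbation_spec("gene_null", outlier_fraction = 0.02)),
      wells = 3L, sites = 8L,
      pipeline_config(target = 200L, replicates = 2L, epochs = 6L,
                      channels = c("nucleus", "actin_membrane_golgi",
                                   "mitochondria"))),
    qc = mk(
      list(perturbation_spec("nontargeting_1", outlier_fraction = 0.02),
           perturbation_spec("KO_outliers", outlier_fraction = 0.30)),
      wells = 1L, sites = 13L,
      pipeline_config(target = 100L, replicates = 1L,
                      channels = "mitochondria", epochs = 4L,
                      qc_reference = "line-median"))
  )
  structure(list(name = name, seed = as.integer(seed),
                 manifest = sc$manifest, config = sc$config),
            class = "BenchmarkScenario")
}

#' Null-calibration run
#'
#' Full pipeline on a zero-effect line; the replicate seeds of the
#' mitochondria-channel classifier supply `n` independent dataset draws and
#' trainings on one simulated screen.
#'
#' @param seed Master seed.
#' @return List with `aucs` (one per replicate seed), `mean_auc`, and the
#'   record table.
#' @export
run_null_calibration <- function(seed = 1L) {
  sc <- benchmark_scenario("null", seed)
  res <- run_screen_pipeline(sc$manifest, sc$config)
  list(aucs = res$records$auc, mean_auc = mean(res$records$auc),
       records = res$records, qc_summary = res$qc_summary)
}

#' Graded effect-recovery run
#'
#' @param seed Master seed.
#' @return List with `by_delta` (data.frame delta, mean_auc) and the record
#'   table.
#' @export
run_graded_recovery <- function(seed = 1L) {
  sc <- benchmark_scenario("graded", seed)
  res <- run_screen_pipeline(sc$manifest, sc$config)
  deltas <- c(KO_mito_000 = 0, KO_mito_050 = 0.5, KO_mito_150 = 1.5)
  by_delta <- data.frame(
    delta = unname(deltas),
    mean_auc = vapply(names(deltas), function(g)
      mean(res$records$auc[res$records$gene_id == g]), numeric(1))
  )
  list(by_delta = by_delta, records = res$records)
}

#' Organelle-attribution recovery run
#'
#' @param seed Master seed.
#' @return List with `attribution` (gene, planted channel, attributed
#'   channel, hit), `accuracy` and the record table.
#' @export
run_attribution_recovery <- function(seed = 1L) {
  sc <- benchmark_scenario("attribution", seed)
  res <- run_screen_pipeline(sc$manifest, sc$config)
  planted <- vapply(sc$manifest$lines[-1], `[[`, character(1),
                    "target_channel")
  names(planted) <- vapply(sc$manifest$lines[-1], `[[`, character(1),
                           "line_id")
  rows <- lapply(names(planted), function(g) {
    att <- attribute_organelle(res$summaries[[g]])
    data.frame(gene_id = g, planted = planted[[g]],
               attributed = att$top_channel, margin = att$margin,
               hit = att$top_channel == planted[[g]],
               stringsAsFactors = FALSE)
  })
  attribution <- do.call(rbind, rows)
  list(attribution = attribution, accuracy = mean(attribution$hit),
       records = res$records)
}

#' Locus prioritization with one strong-effect gene
#'
#' Runs `n_runs` independent two-gene locus screens (one gene with a strong
#' effect in every channel, one null gene) and asks how often the
#' strong-effect gene is prioritized.
#'
#' @param seed Master seed.
#' @param n_runs Number of independent locus screens.
#' @param alpha Significance level.
#' @return List with `hits` (logical per run), `rate` and the comparison
#'   table.
#' @export
run_locus_recovery <- function(seed = 1L, n_runs = 10L, alpha = 0.05) {
  comps <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    sc <- benchmark_scenario("locus", mix_seed(seed, 600L, k))
    res <- run_screen_pipeline(sc$manifest, sc$config)
    comps[[k]] <- compare_locus_genes(
      res$records[res$records$gene_id == "gene_strong", ],
      res$records[res$records$gene_id == "gene_null", ],
      alpha = alpha, locus_id = sprintf("locus_%02d", k))
  }
  comps <- do.call(rbind, comps)
  hits <- !is.na(comps$prioritized_gene) &
    comps$prioritized_gene == "gene_strong"
  list(hits = hits, rate = mean(hits), comparisons = comps)
}

#' Record-level null loci for prioritization type-I calibration
#'
#' Draws AUC records for two genes at a locus from one shared null
#' distribution (normal around 0.5, truncated to \[0,1\], SD matching the
#' dispersion of pipeline null AUCs) and measures how often
#' [compare_locus_genes()] prioritizes either gene. Record-level simulation
#' keeps hundreds of loci tractable; the image-level pipeline is exercised by
#' [run_locus_recovery()].
#'
#' @param seed Master seed.
#' @param n_loci Number of simulated null loci.
#' @param n_records AUC records per gene (25 in the full design).
#' @param sd Null AUC dispersion.
#' @param alpha Significance level.
#' @return List with `rate` (fraction of loci with a prioritized gene),
#'   `mc_se` (Monte-Carlo SE of the rate under p = alpha) and the p values.
#' @export
run_null_locus_calibration <- function(seed = 1L, n_loci = 200L,
                                       n_records = 25L, sd = 0.05,
                                       alpha = 0.05) {
  set.seed(mix_seed(seed, 700L))
  prioritized <- logical(n_loci)
  pvals <- numeric(n_loci)
  for (k in seq_len(n_loci)) {
    a <- pmin(pmax(stats::rnorm(n_records, 0.5, sd), 0), 1)
    b <- pmin(pmax(stats::rnorm(n_records, 0.5, sd), 0), 1)
    cmp <- compare_locus_genes(
      data.frame(gene_id = "a", auc = a), data.frame(gene_id = "b", auc = b),
      alpha = alpha)
    prioritized[k] <- !is.na(cmp$prioritized_gene)
    pvals[k] <- cmp$p_value
  }
  list(rate = mean(prioritized),
       mc_se = sqrt(alpha * (1 - alpha) / n_loci),
       p_values = pvals)
}

#' QC outlier-recovery run
#'
#' Simulates a line with 30 percent planted outlier cells, runs segmentation,
#' cropping, features and the Spearman filter, and scores outlier recall
#' against the generator's ground truth.
#'
#' @param seed Master seed.
#' @param cutoff Filter cutoff.
#' @return List with `recall`, `removed_fraction`, `n_cells` and the joined
#'   per-cell table.
#' @export
run_qc_recovery <- function(seed = 1L, cutoff = 0.15) {
  sc <- benchmark_scenario("qc", seed)
  cells <- collect_screen_cells(sc$manifest, sc$config)
  res <- cells$qc$results
  tab <- merge(res, cells$features[, c("cell_id", "truth_outlier")],
               by = "cell_id")
  tab <- tab[tab$line_id == "KO_outliers" & !is.na(tab$truth_outlier), ]
  recall <- mean(!tab$retained[tab$truth_outlier])
  list(recall = recall,
       removed_fraction = mean(!tab$retained),
       n_cells = nrow(tab), n_outliers = sum(tab$truth_outlier),
       table = tab, features = cells$features)
}

#' Run a named benchmark scenario end to end
#'
#' Dispatches to the scenario runners and returns an evidence table of
#' measured values against the scenario's expectations.
#'
#' @param name Scenario name (see [benchmark_scenario()]).
#' @param seed Master seed.
#' @return List with `evidence` (data.frame: quantity, value, expectation,
#'   pass) and the runner's full result.
#' @export
run_scenario <- function(name = c("null", "graded", "attribution", "locus",
                                  "qc"), seed = 1L) {
  name <- match.arg(name)
  if (name == "null") {
    r <- run_null_calibration(seed)
    ev <- data.frame(
      quantity = c("mean_auc", "min_auc", "max_auc"),
      value = c(r$mean_auc, min(r$aucs), max(r$aucs)),
      expectation = c("in [0.45, 0.55]", ">= 0.40", "<= 0.60"),
      pass = c(r$mean_auc >= 0.45 && r$mean_auc <= 0.55,
               min(r$aucs) >= 0.40, max(r$aucs) <= 0.60))
  } else if (name == "graded") {
    r <- run_graded_recovery(seed)
    inc <- all(diff(r$by_delta$mean_auc) > 0)
    ev <- data.frame(
      quantity = c("monotone_increasing", "strong_delta_auc"),
      value = c(as.numeric(inc), r$by_delta$mean_auc[3]),
      expectation = c("strictly increasing in delta", ">= 0.95"),
      pass = c(inc, r$by_delta$mean_auc[3] >= 0.95))
  } else if (name == "attribution") {
    r <- run_attribution_recovery(seed)
    ev <- data.frame(quantity = "attribution_accuracy", value = r$accuracy,
                     expectation = ">= 0.9", pass = r$accuracy >= 0.9)
  } else if (name == "locus") {
    r <- run_locus_recovery(seed)
    n <- run_null_locus_calibration(seed)
    ev <- data.frame(
      quantity = c("strong_gene_prioritization_rate",
                   "null_prioritization_rate"),
      value = c(r$rate, n$rate),
      expectation = c(">= 0.9", sprintf("<= %.3f", 0.05 + 2 * n$mc_se)),
      pass = c(r$rate >= 0.9, n$rate <= 0.05 + 2 * n$mc_se))
    r <- list(locus = r, null_locus = n)
  } else {
    r <- run_qc_recovery(seed)
    ev <- data.frame(
      quantity = c("outlier_recall", "removed_fraction"),
      value = c(r$recall, r$removed_fraction),
      expectation = c(">= 0.8", "reported"),
      pass = c(r$recall >= 0.8, NA))
  }
  list(evidence = ev, result = r)
}
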