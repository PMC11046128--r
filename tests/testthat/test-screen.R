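make_records <- function(gene, aucs, channels = channel_names(),
                         reps = seq_len(ceiling(length(aucs) /
                                                  length(channels)))) {
  grid <- expand.grid(channel = channels, replicate_seed = reps,
                      stringsAsFactors = FALSE)[seq_along(aucs), ]
  data.frame(gene_id = gene, channel = grid$channel,
             replicate_seed = grid$replicate_seed, auc = aucs,
             n_test_pos = 30L, n_test_neg = 30L, stringsAsFactors = FALSE)
}

test_that("gene aggregation reproduces direct mean/SD formulas", {
  rec <- make_records("G1", rep(0.7, 25))
  s <- aggregate_gene(rec)
  expect_equal(s$mean_auc, 0.7)
  expect_equal(s$sd_auc, 0)
  expect_true(s$complete)
  expect_equal(s$n_records, 25L)

  rec2 <- make_records("G2", c(0.6, 0.8), channels = "mitochondria",
                       reps = 1:2)
  s2 <- aggregate_gene(rec2)
  expect_equal(s2$mean_auc, 0.7)
  expect_equal(s2$sd_auc, sd(c(0.6, 0.8)), tolerance = 1e-12)
  expect_equal(round(s2$sd_auc, 4), 0.1414)
  expect_false(s2$complete)

  # permutation invariance and duplicate detection
  rec3 <- make_records("G3", seq(0.5, 0.74, by = 0.01))
  expect_equal(aggregate_gene(rec3)$mean_auc,
               aggregate_gene(rec3[sample(25), ])$mean_auc)
  dup <- rbind(rec3, rec3[1, ])
  expect_error(aggregate_gene(dup), "duplicate")
  expect_error(aggregate_gene(rbind(rec, rec2)), "one gene_id")
})

test_that("aggregation conserves the replicate-weighted channel means", {
  set.seed(13)
  rec <- make_records("G", runif(25, 0.4, 0.9))
  s <- aggregate_gene(rec)
  expect_equal(s$mean_auc, mean(s$per_channel_mean_auc), tolerance = 1e-12)
})

test_that("organelle attribution takes the argmax with fixed-order ties", {
  rec <- make_records("G", rep(c(0.60, 0.65, 0.62, 0.61, 0.75), 5))
  att <- attribute_organelle(aggregate_gene(rec))
  expect_identical(att$top_channel, "mitochondria")
  expect_equal(att$margin, 0.10, tolerance = 1e-12)
  expect_false(att$tie)

  tied <- make_records("G", rep(0.7, 25))
  att2 <- attribute_organelle(aggregate_gene(tied))
  expect_identical(att2$top_channel, "nucleus")  # first in fixed order
  expect_true(att2$tie)

  part <- make_records("G", rep(0.7, 10),
                       channels = channel_names()[1:2], reps = 1:5)
  expect_error(attribute_organelle(aggregate_gene(part)), "missing")
})

test_that("locus comparison handles identity and degenerate inputs exactly", {
  a <- make_records("A", rep(0.7, 10), channels = "mitochondria", reps = 1:10)
  cmp <- compare_locus_genes(a, transform(a, gene_id = "B"))
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$delta_mean_auc, 0)
  expect_true(is.na(cmp$prioritized_gene))

  b0 <- make_records("B", rep(0.9, 10), channels = "mitochondria", reps = 1:10)
  cmp2 <- compare_locus_genes(a, b0)
  expect_equal(cmp2$p_value, 0)          # zero variance, different means
  expect_identical(cmp2$prioritized_gene, "B")

  expect_error(compare_locus_genes(a[1, ], b0), "at least 2")
})

test_that("the Welch test agrees with a permutation oracle", {
  a <- make_records("A", c(0.80, 0.82, 0.78, 0.81, 0.79),
                    channels = "mitochondria", reps = 1:5)
  b <- make_records("B", c(0.60, 0.62, 0.58, 0.61, 0.59),
                    channels = "mitochondria", reps = 1:5)
  cmp <- compare_locus_genes(a, b)
  expect_lt(cmp$p_value, 0.01)
  expect_identical(cmp$prioritized_gene, "A")
  # exact permutation oracle over all 252 assignments
  pool <- c(a$auc, b$auc)
  obs <- abs(mean(a$auc) - mean(b$auc))
  combs <- utils::combn(10, 5)
  perm <- mean(apply(combs, 2, function(idx)
    abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12))
  expect_equal(perm, 2 / 252)            # only the observed split and mirror
  expect_lt(cmp$p_value, 0.05)

  # on overlapping samples the two tests agree numerically
  set.seed(31)
  x <- make_records("A", rnorm(12, 0.65, 0.05), channels = "mitochondria",
                    reps = 1:12)
  y <- make_records("B", rnorm(12, 0.61, 0.05), channels = "mitochondria",
                    reps = 1:12)
  cmp2 <- compare_locus_genes(x, y)
  pool <- c(x$auc, y$auc)
  obs <- abs(mean(x$auc) - mean(y$auc))
  set.seed(32)
  perm2 <- mean(replicate(10000, {
    idx <- sample(24, 12)
    abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
  }))
  expect_lt(abs(cmp2$p_value - perm2), 0.05)
})

test_that("screen reports are deterministic and complete", {
  s1 <- aggregate_gene(make_records("G1", rep(0.8, 25)))
  s2 <- aggregate_gene(make_records("G2", rep(0.6, 25)))
  cmp <- compare_locus_genes(make_records("G1", rep(0.8, 25)),
                             make_records("G2", rep(0.6, 25)),
                             locus_id = "rs0001")
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- write_screen_report(list(s1, s2), cmp, dir1)
  p2 <- write_screen_report(list(s1, s2), cmp, dir2)
  rank1 <- utils::read.csv(p1$ranking)
  expect_equal(rank1$gene_id, c("G1", "G2"))   # ranked by mean AUC
  expect_identical(readLines(p1$ranking), readLines(p2$ranking))
  expect_identical(readLines(p1$report), readLines(p2$report))
  rep1 <- jsonlite::read_json(p1$report)
  expect_equal(sum(unlist(rep1$channel_fractions)), 1)
})
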