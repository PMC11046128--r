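test_that("field rendering is bit-reproducible and respects its contract", {
  geom <- small_geom(cells = 8L)
  spec <- perturbation_spec("ctrl")
  f1 <- render_field(spec, seed = 42, geom = geom)
  f2 <- render_field(spec, seed = 42, geom = geom)
  expect_identical(f1$pixels, f2$pixels)
  expect_identical(f1$truth, f2$truth)
  expect_equal(dim(f1$pixels), c(192L, 192L, 5L))
  expect_true(all(is.finite(f1$pixels)))
  expect_true(min(f1$pixels) >= 0 && max(f1$pixels) <= 1)
  expect_equal(nrow(f1$truth), 8L)
  f3 <- render_field(spec, seed = 43, geom = geom)
  expect_false(identical(f1$pixels, f3$pixels))
})

test_that("impossible cell placement fails with an explicit error", {
  geom <- field_geometry(field_size = 96, cell_radius = 13,
                         cells_per_field = 40L)
  expect_error(render_field(perturbation_spec("ctrl"), seed = 1, geom = geom),
               "unable to place")
})

test_that("per-channel effects move only their own channel's parameters", {
  base <- morphoscreen:::control_baselines()
  pert <- morphoscreen:::perturbed_params(stats::setNames(c(0, 0, 0, 0, 1.5),
                                                          channel_names()))
  expect_identical(pert$nucleus, base$nucleus)
  expect_identical(pert$actin_membrane_golgi, base$actin_membrane_golgi)
  expect_gt(pert$mitochondria$density, base$mitochondria$density)
  expect_identical(morphoscreen:::perturbed_params(
    stats::setNames(rep(0, 5), channel_names())), base)
})

test_that("zero-effect line is indistinguishable from control", {
  geom <- field_geometry(field_size = 128, cell_radius = 13,
                         cells_per_field = 5L)
  mito <- channel_slot("mitochondria")
  mean_int <- function(line, base_seed) {
    vapply(seq_len(40), function(i) {
      f <- render_field(perturbation_spec(line), seed = base_seed + i,
                        geom = geom)
      mean(f$pixels[, , mito])
    }, numeric(1))
  }
  ctrl <- mean_int("ctrl", 5000)
  null_ko <- mean_int("ko_null", 6000)
  expect_gt(stats::wilcox.test(ctrl, null_ko)$p.value, 0.01)
})

test_that("planted mitochondrial puncta counts increase with effect size", {
  geom <- small_geom(cells = 10L)
  counts <- vapply(c(0, 0.5, 1.5), function(d) {
    spec <- perturbation_spec("ko", effects = c(mitochondria = d))
    mean(vapply(1:8, function(i)
      mean(render_field(spec, seed = 300 + i, geom = geom)$truth$mito_count),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("screen simulation has the promised layout and determinism", {
  lines <- list(perturbation_spec("ctrl"),
                perturbation_spec("koA", effects = c(mitochondria = 1)),
                perturbation_spec("koB", effects = c(nucleus = 1)))
  man <- sim_manifest(lines, wells_per_line = 2L, sites_per_well = 3L,
                      seed = 9, geom = small_geom(cells = 6L))
  sim <- simulate_screen(man)
  expect_length(sim$fields, 18L)
  expect_equal(nrow(sim$lines), 3L)
  expect_equal(sim$lines$n_cells, rep(36L, 3))
  # conservation: planted cells equal ground-truth totals
  expect_equal(nrow(sim$cells), sum(sim$lines$n_cells))
  sim2 <- simulate_screen(man)
  expect_identical(sim$cells, sim2$cells)
  expect_identical(sim$fields[[7]]$pixels, sim2$fields[[7]]$pixels)
  expect_error(sim_manifest(list(perturbation_spec("x"),
                                 perturbation_spec("x"))),
               "duplicate line_id")
})

test_that("outlier planting follows the requested fraction binomially", {
  man <- sim_manifest(list(perturbation_spec("ko", outlier_fraction = 0.3)),
                      wells_per_line = 2L, sites_per_well = 5L, seed = 4,
                      geom = small_geom(cells = 10L))
  sim <- simulate_screen(man)
  n <- nrow(sim$cells)
  expect_equal(n, 100L)
  k <- sum(sim$cells$outlier)
  expect_lt(abs(k - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7))
  expect_equal(sim$lines$n_outliers, k)
})

test_that("invalid perturbation specs are rejected", {
  expect_error(perturbation_spec("x", effects = c(bogus = 1)), "channel")
  expect_error(perturbation_spec("x", effects = c(mitochondria = -1)),
               ">= 0")
  expect_error(perturbation_spec("x", outlier_fraction = 1.2), "0, 1")
  sp <- perturbation_spec("x", effects = c(nucleus = 0.2, mitochondria = 0.9))
  expect_identical(sp$target_channel, "mitochondria")
  expect_identical(perturbation_spec("y")$target_channel, NA_character_)
})
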