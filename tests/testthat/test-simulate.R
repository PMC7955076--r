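test_that("cohort simulation is deterministic and shaped correctly", {
  atlas <- tiny_atlas(10)
  truth <- simulation_truth(atlas, effect_regions = c(1, 2),
                            effect_direction = c(1, -1), effect_size = 2,
                            seed = 3)
  c1 <- simulate_cohort(atlas, 5, 4, truth)
  c2 <- simulate_cohort(atlas, 5, 4, truth)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$features), 10 * 20)
  expect_equal(names(c1$features), c("subject_id", "region_id", paste0("f", 1:4)))
  expect_equal(nrow(c1$participants), 10)
  expect_true(all(c("age", "sex", "education", "tiv", "hamd", "hama") %in%
                    names(c1$participants)))
  expect_error(simulation_truth(atlas, effect_regions = 999),
               class = "invalid_argument")
  expect_error(simulate_cohort(atlas, 5, 2, truth), class = "invalid_argument")
})

test_that("with zero effect the group t-statistics behave like a null", {
  # regional t's are correlated within a cohort, so aggregate across seeds
  stats_by_seed <- vapply(9:12, function(s) {
    atlas <- tiny_atlas(15)
    truth <- simulation_truth(atlas, effect_size = 0, seed = s)
    coh <- simulate_cohort(atlas, 20, 7, truth)
    tm <- fit_tmap(compute_strengths(coh$features), coh$participants)
    c(mean_abs_t = mean(abs(tm$t)), discoveries = sum(tm$q < 0.05))
  }, numeric(2))
  expect_lt(mean(stats_by_seed["mean_abs_t", ]), 1.2)
  expect_gt(mean(stats_by_seed["mean_abs_t", ]), 0.5)
  expect_lte(mean(stats_by_seed["discoveries", ]), 0.5)
})

test_that("planted effects produce sign-consistent t-statistics across seeds", {
  atlas <- make_atlas(40, 7)
  eff <- msntx:::plant_effect_regions(atlas, 10)
  hits <- vapply(1:8, function(s) {
    truth <- simulation_truth(atlas, eff$regions, eff$direction,
                              effect_size = 3, seed = s)
    coh <- simulate_cohort(atlas, 30, 7, truth)
    tm <- fit_tmap(compute_strengths(coh$features), coh$participants)
    mean(sign(tm$t[match(eff$regions, tm$region_id)]) == eff$direction)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("expression bundles are deterministic with conserved counts", {
  atlas <- tiny_atlas(8)
  left_ids <- atlas$region_id[atlas$hemisphere == "L"]
  sm <- stats::setNames(seq_along(left_ids), left_ids)
  truth <- simulation_truth(atlas, planted_genes = c("pg1", "pg2"),
                            planted_sign = c(1, -1), seed = 4)
  b1 <- simulate_expression_bundle(atlas, n_genes = 20, probes_per_gene = 3,
                                   n_donors = 2, samples_per_donor = 15,
                                   signal_map = sm, truth = truth)
  b2 <- simulate_expression_bundle(atlas, n_genes = 20, probes_per_gene = 3,
                                   n_donors = 2, samples_per_donor = 15,
                                   signal_map = sm, truth = truth)
  expect_identical(b1, b2)
  for (don in b1$donors) {
    expect_equal(nrow(don$expression), 60)     # 3 probes x 20 genes
    expect_equal(dim(don$pacall), dim(don$expression))
  }
  expect_equal(nrow(b1$probes), 60)
  expect_error(
    simulate_expression_bundle(atlas, 20, 2, n_donors = 1,
                               samples_per_donor = 5, signal_map = sm,
                               truth = truth),
    class = "invalid_argument")
  expect_error(
    simulate_expression_bundle(atlas, 1, 2, n_donors = 2,
                               samples_per_donor = 5, signal_map = sm,
                               truth = truth),
    class = "invalid_argument")
})

test_that("a noise-free planted gene reproduces the signal map exactly", {
  atlas <- tiny_atlas(10)
  left_ids <- atlas$region_id[atlas$hemisphere == "L"]
  sm <- withr::with_seed(5, stats::setNames(rnorm(10), left_ids))
  truth <- simulation_truth(atlas, planted_genes = "pg1", planted_sign = 1,
                            seed = 6)
  b <- simulate_expression_bundle(atlas, n_genes = 5, probes_per_gene = 1,
                                  n_donors = 2, samples_per_donor = 30,
                                  signal_map = sm, truth = truth,
                                  profile_sd = 0, probe_noise_sd = 0,
                                  jitter_sd = 0, right_frac = 0, far_frac = 0,
                                  low_probe_frac = 0, bad_annotation_frac = 0,
                                  background_quantile = 0, ref_noise_sd = 0)
  prof <- b$meta$profiles[as.character(left_ids), "pg1"]
  expect_equal(cor(prof, sm), 1, tolerance = 1e-12)
})

test_that("DGE tables track planted loadings at the requested strength", {
  atlas <- tiny_atlas(6)
  truth <- simulation_truth(atlas, planted_genes = paste0("pg", 1:15),
                            planted_sign = rep_len(c(1, -1), 15), seed = 8)
  dge <- simulate_dge_table(truth, n_background = 50, corr_strength = 1)
  expect_equal(nrow(dge), 65)
  planted <- dge[match(truth$planted_genes, dge$gene), ]
  expect_equal(cor(planted$dge_value, truth$planted_loading,
                   method = "spearman"), -1)
  expect_true(all(dge$direction[dge$dge_value > 0] == "up"))

  d0 <- simulate_dge_table(truth, 50, corr_strength = 0, seed = 99)
  expect_lt(abs(cor(d0$dge_value[match(truth$planted_genes, d0$gene)],
                    truth$planted_loading, method = "spearman")), 0.9)
  expect_identical(simulate_dge_table(truth, 10, 0.5),
                   simulate_dge_table(truth, 10, 0.5))
})

test_that("cell sets respect sizes, enrichment and forced containment", {
  universe <- c(paste0("pg", 1:10), paste0("bg", 1:90))
  sets <- make_cell_sets(universe, 7, class_sizes = 12,
                         enrichment = c(1, rep(0, 6)) * 10 / 12,
                         planted_genes = paste0("pg", 1:10), seed = 2)
  expect_length(sets, 7)
  expect_named(sets, c("astrocytes", "endothelial", "excitatory_neurons",
                       "inhibitory_neurons", "microglia", "OPCs",
                       "oligodendrocytes"))
  expect_true(all(lengths(sets) == 12))
  expect_equal(length(intersect(sets$astrocytes, paste0("pg", 1:10))), 10)
  # enrichment 1.0 on a class the size of the planted set forces containment
  s2 <- make_cell_sets(universe, 1, class_sizes = 10, enrichment = 1,
                       planted_genes = paste0("pg", 1:10), seed = 3)
  expect_setequal(s2[[1]], paste0("pg", 1:10))
  expect_error(make_cell_sets(universe, 2, class_sizes = 200),
               class = "invalid_argument")
})

test_that("cohort and bundle writers round-trip through disk", {
  atlas <- tiny_atlas(6)
  truth <- simulation_truth(atlas, seed = 12)
  coh <- simulate_cohort(atlas, 3, 4, truth)
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  back <- read_cohort(d)
  expect_equal(back$features, coh$features, tolerance = 1e-12)

  left_ids <- atlas$region_id[atlas$hemisphere == "L"]
  sm <- stats::setNames(seq_along(left_ids), left_ids)
  b <- simulate_expression_bundle(atlas, 10, 2, 2, 10, sm, truth)
  bd <- file.path(d, "bundle")
  write_bundle_csvs(b, bd)
  back_b <- read_bundle_csvs(bd)
  expect_equal(back_b$donors$donor_01$expression, b$donors$donor_01$expression,
               tolerance = 1e-10)
  expect_equal(back_b$donors$donor_02$pacall, b$donors$donor_02$pacall,
               ignore_attr = TRUE)
  expect_equal(back_b$radius, b$radius)
})
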