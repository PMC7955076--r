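test_that("re-annotation drops missing, ambiguous and contradicted probes", {
  probes <- tibble::tibble(probe_id = 1:10,
                           gene_symbol = paste0("g", 1:10))
  mapping <- tibble::tibble(
    probe_id = c(1:7, 5, 6),                       # 8..10 missing
    gene_symbol = c(paste0("g", 1:4), "gX", "g6", "g7", "g5", "gY")
  )
  # probe 5: ambiguous (gX and g5); probe 6: ambiguous (g6, gY);
  # probes 8..10 missing -> 10 - 2 - 3 = 5 survive... but probe 5/6 are the
  # ambiguous ones and the rest agree
  out <- reannotate_probes(probes, mapping)
  expect_equal(out$probe_id, c(1:4, 7))
  expect_equal(attr(out, "dropped"),
               c(missing = 3L, ambiguous = 2L, contradicted = 0L))

  mapping2 <- tibble::tibble(probe_id = 1:10,
                             gene_symbol = c(paste0("g", 1:9), "WRONG"))
  out2 <- reannotate_probes(probes, mapping2)
  expect_equal(attr(out2, "dropped")[["contradicted"]], 1L)
  expect_false(10 %in% out2$probe_id)

  expect_error(reannotate_probes(probes,
                                 tibble::tibble(probe_id = 99,
                                                gene_symbol = "z")),
               class = "pipeline_halt")
})

test_that("intensity filtering pools present calls across donors at the 50% default", {
  b <- tiny_bundle()
  # probe 101 present in 100%; 102 present in 5 of 12 pooled samples (41.7%);
  # 103 present in exactly 6 of 12 (50%)
  b$donors$donor_1$pacall[2, ] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  b$donors$donor_2$pacall[2, ] <- c(1L, 1L, 0L, 0L, 0L, 0L)
  b$donors$donor_1$pacall[3, ] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  b$donors$donor_2$pacall[3, ] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  keep <- filter_probes_intensity(b)
  expect_true(101 %in% keep)
  expect_false(102 %in% keep)     # 0.417 < 0.5 boundary
  expect_true(103 %in% keep)      # exactly 0.5 is kept
  frac <- attr(keep, "present_fraction")
  expect_equal(unname(frac[["102"]]), 5 / 12)
})

test_that("probe selection maximizes reference correlation with tie-breaks", {
  b <- tiny_bundle()
  # make probe 102 track g1's reference much better than 101
  ref_g1 <- b$reference["g1", ]
  for (d in names(b$donors)) {
    str_ <- b$donors[[d]]$samples$structure_id
    b$donors[[d]]$expression["102", ] <- as.numeric(ref_g1[as.character(str_)])
    b$donors[[d]]$expression["101", ] <- rev(as.numeric(ref_g1[as.character(str_)]))
  }
  sel <- select_probes(b, probe_ids = c(101L, 102L, 103L, 104L))
  expect_equal(sel$probe_id[sel$gene_symbol == "g1"], 102L)
  expect_equal(sel$rule[sel$gene_symbol == "g1"], "reference_correlation")
  # single surviving probe is selected regardless
  expect_equal(sel$probe_id[sel$gene_symbol == "g2"], 103L)

  # exact tie -> lower probe_id wins
  for (d in names(b$donors)) {
    b$donors[[d]]$expression["101", ] <- b$donors[[d]]$expression["102", ]
  }
  sel2 <- select_probes(b, probe_ids = c(101L, 102L, 103L, 104L))
  expect_equal(sel2$probe_id[sel2$gene_symbol == "g1"], 101L)

  # gene absent from the reference falls back to mean intensity
  b3 <- tiny_bundle()
  b3$reference <- b3$reference[c("g1", "g2"), ]
  for (d in names(b3$donors)) b3$donors[[d]]$expression["104", ] <- 20
  sel3 <- select_probes(b3, probe_ids = c(101L, 102L, 103L, 104L))
  expect_equal(sel3$rule[sel3$gene_symbol == "g3"], "mean_intensity")
})

test_that("sample assignment matches a brute-force nearest-neighbour scan", {
  atlas <- tiny_atlas(8)
  truth <- simulation_truth(atlas, seed = 20)
  left_ids <- atlas$region_id[atlas$hemisphere == "L"]
  sm <- stats::setNames(seq_along(left_ids), left_ids)
  b <- simulate_expression_bundle(atlas, 10, 1, 2, 40, sm, truth,
                                  right_frac = 0.2, far_frac = 0.2)
  asn <- assign_samples(b, atlas, max_distance = 2, left_only = FALSE)
  rep_points <- b$radius * atlas_centroids(atlas)
  k <- 1
  for (don in b$donors) {
    pos <- as.matrix(don$samples[, c("mni_x", "mni_y", "mni_z")])
    for (i in seq_len(nrow(pos))) {
      dd <- sqrt(colSums((t(rep_points) - pos[i, ])^2))
      j <- which.min(dd)
      expected <- if (dd[j] <= 2) atlas$region_id[j] else NA_integer_
      expect_identical(asn$region_id[k], expected)
      k <- k + 1
    }
  }
  # left-only drops right-hemisphere assignments
  asn_l <- assign_samples(b, atlas, 2, left_only = TRUE)
  right_ids <- atlas$region_id[atlas$hemisphere == "R"]
  expect_false(any(asn_l$region_id %in% right_ids, na.rm = TRUE))
  expect_gt(sum(is.na(asn_l$region_id)), sum(is.na(asn$region_id)))
})

test_that("a sample exactly at a representative point is assigned there", {
  atlas <- tiny_atlas(6)
  b <- tiny_bundle()
  pt <- 75 * as.numeric(atlas[3, c("cx", "cy", "cz")])
  b$donors$donor_1$samples$mni_x <- pt[1]
  b$donors$donor_1$samples$mni_y <- pt[2]
  b$donors$donor_1$samples$mni_z <- pt[3]
  asn <- assign_samples(b, atlas, 2)
  expect_true(all(asn$region_id[asn$donor_id == "donor_1"] == 3))
  expect_true(all(asn$distance[asn$donor_id == "donor_1"] < 1e-9))
})

test_that("scaled robust sigmoid maps into [0,1], preserves order, centres at the median", {
  x <- withr::with_seed(30, matrix(rnorm(40, 5, 2), 20, 2,
                                   dimnames = list(NULL, c("a", "b"))))
  out <- srs_normalize(x)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(order(out[, 1]), order(x[, 1]))   # strictly monotone

  # implementation equals the plug-in formula; at the median the raw sigmoid
  # is exactly 0.5
  v <- x[, 1]
  s_raw <- 1 / (1 + exp(-(v - median(v)) / stats::IQR(v)))
  expect_equal(out[, 1], (s_raw - min(s_raw)) / (max(s_raw) - min(s_raw)),
               tolerance = 1e-12)
  v5 <- c(1, 2, 3, 4, 10)
  expect_equal(1 / (1 + exp(-(3 - median(v5)) / stats::IQR(v5))), 0.5)
  out5 <- srs_normalize(matrix(v5, ncol = 1, dimnames = list(NULL, "g")))
  expect_equal(order(out5), order(v5))

  # zero-IQR genes become 0.5 and are flagged
  x2 <- cbind(x, flat = 3)
  out2 <- srs_normalize(x2)
  expect_true(all(out2[, "flat"] == 0.5))
  expect_equal(attr(out2, "flagged_genes"), "flat")
})

test_that("differential stability matches brute-force mean pairwise Spearman", {
  withr::with_seed(40, {
    mats <- lapply(1:3, function(d) {
      m <- matrix(rnorm(8 * 5), 8, 5,
                  dimnames = list(1:8, paste0("g", 1:5)))
      m
    })
  })
  res <- differential_stability_filter(mats, "ds_min", threshold = -1)
  for (g in paste0("g", 1:5)) {
    pairs <- utils::combn(3, 2)
    rhos <- apply(pairs, 2, function(pr) {
      oracle_spearman(mats[[pr[1]]][, g], mats[[pr[2]]][, g])
    })
    expect_equal(res$ds$ds[res$ds$gene == g], mean(rhos), tolerance = 1e-12)
  }
  # identical profiles give DS = 1 and survive any positive threshold
  mats2 <- list(mats[[1]], mats[[1]])
  rownames(mats2[[2]]) <- rownames(mats2[[1]])
  res2 <- differential_stability_filter(mats2, "ds_min", threshold = 0.99)
  expect_equal(res2$ds$ds, rep(1, 5), tolerance = 1e-12)
  expect_equal(res2$genes, paste0("g", 1:5))
  # top_fraction keeps the requested share
  res3 <- differential_stability_filter(mats, "top_fraction", 0.4)
  expect_length(res3$genes, 2)
  expect_error(differential_stability_filter(mats[1], "ds_min", 0),
               class = "invalid_argument")
})

test_that("noise-free pipelines conserve gene profiles and log exact provenance", {
  atlas <- make_atlas(12, 3)
  left_ids <- atlas$region_id[atlas$hemisphere == "L"]
  truth <- simulation_truth(atlas, planted_genes = c("pg1", "pg2"),
                            planted_sign = c(1, -1), seed = 50)
  sm <- withr::with_seed(51, stats::setNames(rnorm(12), left_ids))
  b <- simulate_expression_bundle(
    atlas, n_genes = 30, probes_per_gene = 1, n_donors = 3,
    samples_per_donor = 15, signal_map = sm, truth = truth,
    probe_noise_sd = 0, jitter_sd = 0, right_frac = 0, far_frac = 0,
    low_probe_frac = 0, bad_annotation_frac = 0, background_quantile = 0,
    coverage = "complete", ref_noise_sd = 0
  )
  rgm <- build_region_gene_matrix(b, atlas, list(ds_mode = "none"))
  expect_true(all(rgm$values >= 0 & rgm$values <= 1))
  # all rows are left-hemisphere regions
  expect_setequal(as.integer(rownames(rgm$values)), left_ids)
  # per gene, Spearman with the generating profile is exactly 1
  for (g in colnames(rgm$values)) {
    prof <- b$meta$profiles[rownames(rgm$values), g]
    expect_equal(cor(rgm$values[, g], prof, method = "spearman"), 1,
                 tolerance = 1e-12)
  }
  pr <- rgm$provenance
  expect_equal(pr$n_probes_initial, 30)
  expect_equal(sum(pr$reannotation_dropped), 0)
  expect_equal(pr$n_probes_dropped_intensity, 0)
  expect_equal(pr$n_genes_selected, 30)
  expect_equal(pr$n_samples_unassigned, 0)
  expect_equal(pr$n_regions, 12)
})

test_that("planted-bad probes are exactly the ones the pipeline drops", {
  atlas <- tiny_atlas(10)
  left_ids <- atlas$region_id[atlas$hemisphere == "L"]
  truth <- simulation_truth(atlas, planted_genes = "pg1", seed = 60)
  sm <- stats::setNames(seq_along(left_ids), left_ids)
  # background_quantile equal to the planted-low-probe mass fraction puts
  # the detection threshold in the intensity gap between failed and working
  # probes, so the intensity filter drops exactly the planted-low probes and
  # the bookkeeping is exact
  b <- simulate_expression_bundle(atlas, n_genes = 40, probes_per_gene = 3,
                                  n_donors = 3, samples_per_donor = 60,
                                  signal_map = sm, truth = truth,
                                  background_quantile = 8 / 120,
                                  coverage = "complete")
  rgm <- build_region_gene_matrix(b, atlas, list(ds_mode = "none"))
  pr <- rgm$provenance
  expect_equal(sum(pr$reannotation_dropped), length(b$meta$bad_probes))
  expect_equal(pr$n_probes_dropped_intensity, length(b$meta$low_probes))
  expect_equal(pr$n_genes_selected, 40)
  # the high-fidelity probe wins for nearly every gene
  hit <- mean(rgm$selection$probe_id ==
                b$meta$best_probe[rgm$selection$gene_symbol])
  expect_gte(hit, 0.9)
})

test_that("pipeline output is invariant to donor order", {
  atlas <- tiny_atlas(8)
  left_ids <- atlas$region_id[atlas$hemisphere == "L"]
  truth <- simulation_truth(atlas, seed = 70)
  sm <- stats::setNames(seq_along(left_ids), left_ids)
  b <- simulate_expression_bundle(atlas, 15, 2, 3, 40, sm, truth,
                                  coverage = "complete")
  b_rev <- b
  b_rev$donors <- rev(b$donors)
  r1 <- build_region_gene_matrix(b, atlas, list(ds_mode = "none"))
  r2 <- build_region_gene_matrix(b_rev, atlas, list(ds_mode = "none"))
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
})
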