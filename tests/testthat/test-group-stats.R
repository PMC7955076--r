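make_null_cohort <- function(n_per_group = 12, n_regions = 8, seed = 5) {
  withr::with_seed(seed, {
    participants <- tibble::tibble(
      subject_id = sprintf("s%02d", 1:(2 * n_per_group)),
      group = rep(c("case", "control"), each = n_per_group),
      age = rnorm(2 * n_per_group, 35, 10),
      sex = rbinom(2 * n_per_group, 1, 0.5),
      education = rnorm(2 * n_per_group, 12, 3)
    )
    strengths <- tidyr::expand_grid(subject_id = participants$subject_id,
                                    region_id = seq_len(n_regions))
    strengths$strength <- rnorm(nrow(strengths))
    list(strengths = strengths, participants = participants)
  })
}

test_that("BH adjustment equals the step-up oracle, including on subsets", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  grid <- c(0.001, 0.01, 0.04, 0.2, 0.5, 0.9)
  for (k in 1:6) {
    for (idx in utils::combn(6, k, simplify = FALSE)) {
      expect_equal(bh_fdr(grid[idx]), oracle_bh(grid[idx]), tolerance = 1e-12)
    }
  }
  expect_error(bh_fdr(c(0.1, 1.2)), class = "invalid_argument")
  expect_error(bh_fdr(c(-0.1)), class = "invalid_argument")
})

test_that("per-region t-statistics match the normal-equations oracle", {
  nc <- make_null_cohort(10, 6)
  # plant a group effect in region 3
  idx <- nc$strengths$region_id == 3 &
    nc$strengths$subject_id %in% nc$participants$subject_id[nc$participants$group == "case"]
  nc$strengths$strength[idx] <- nc$strengths$strength[idx] + 3
  tm <- fit_tmap(nc$strengths, nc$participants)

  x <- cbind(1, as.numeric(nc$participants$group == "case"),
             nc$participants$age, nc$participants$sex, nc$participants$education)
  for (r in 1:6) {
    y <- nc$strengths$strength[nc$strengths$region_id == r]
    y <- y[match(nc$participants$subject_id,
                 nc$strengths$subject_id[nc$strengths$region_id == r])]
    o <- oracle_ols_t(y, x)
    expect_equal(tm$t[tm$region_id == r], o$t, tolerance = 1e-10)
    expect_equal(tm$p[tm$region_id == r], o$p, tolerance = 1e-10)
  }
  expect_equal(tm$q, bh_fdr(tm$p))
  expect_gt(tm$t[tm$region_id == 3], 2)
})

test_that("t-map is exactly equivariant under group-label swap", {
  nc <- make_null_cohort(8, 5, seed = 11)
  tm1 <- fit_tmap(nc$strengths, nc$participants)
  swapped <- nc$participants
  swapped$group <- ifelse(swapped$group == "case", "control", "case")
  tm2 <- fit_tmap(nc$strengths, swapped)
  expect_equal(tm2$t, -tm1$t, tolerance = 1e-12)
})

test_that("a covariate orthogonal to group and strength leaves t unchanged", {
  nc <- make_null_cohort(10, 4, seed = 3)
  tm1 <- fit_tmap(nc$strengths, nc$participants, covariates = c("age"))
  # residualize a random covariate against [1, group, age] and the outcomes
  x <- cbind(1, as.numeric(nc$participants$group == "case"), nc$participants$age)
  y <- sapply(1:4, function(r) {
    s <- nc$strengths[nc$strengths$region_id == r, ]
    s$strength[match(nc$participants$subject_id, s$subject_id)]
  })
  z <- withr::with_seed(8, rnorm(nrow(x)))
  m <- cbind(x, y)
  z <- z - m %*% solve(crossprod(m), crossprod(m, z))
  pp <- nc$participants
  pp$orth <- as.numeric(z)
  tm2 <- fit_tmap(nc$strengths, pp, covariates = c("age", "orth"))
  expect_equal(tm2$t, tm1$t * sqrt((attr(tm2, "df")) / attr(tm1, "df")) /
                 sqrt(1), tolerance = 1e-6)
})

test_that("null cohorts give well-behaved t-maps with no discoveries", {
  nc <- make_null_cohort(15, 20, seed = 21)
  tm <- fit_tmap(nc$strengths, nc$participants)
  expect_lt(mean(abs(tm$t)), 1.3)
  expect_equal(sum(tm$q < 0.05), 0)
})

test_that("fit_tmap validates its design", {
  nc <- make_null_cohort(3, 4)
  expect_error(fit_tmap(nc$strengths, nc$participants), class = "invalid_argument")
  nc2 <- make_null_cohort(10, 4)
  nc2$participants$dup <- nc2$participants$age
  expect_error(fit_tmap(nc2$strengths, nc2$participants,
                        covariates = c("age", "dup")),
               class = "singular_design")
})

test_that("quadrant classification follows the strict-sign rules", {
  tmap <- tibble::tibble(region_id = 1:5, t = c(-2, 2, 2, -2, 0),
                         p = 0.5, q = 0.5)
  ms <- tibble::tibble(region_id = 1:5, strength = c(3, -3, 3, -3, 1))
  q <- classify_regions(tmap, ms)
  expect_equal(q$label, c("decoupling", "dedifferentiation", "coupled_increase",
                          "differentiated_decrease", "null"))
  frac <- attr(q, "fractions")
  expect_equal(sum(frac), 1)
  expect_equal(as.numeric(frac), rep(0.2, 5))
})

test_that("a single system covering all regions collapses to the grand mean", {
  nc <- make_null_cohort(10, 6, seed = 2)
  atlas <- make_atlas(4, 1)[1:6, ]
  atlas$region_id <- 1:6
  atlas$yeo7 <- "system_1"
  sys <- aggregate_by_system(nc$strengths, atlas, "yeo7", nc$participants)
  gm <- nc$strengths |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(strength = mean(strength), .groups = "drop")
  gm$region_id <- 1L
  tm <- fit_tmap(gm, nc$participants)
  expect_equal(sys$t, tm$t, tolerance = 1e-12)
  expect_error(aggregate_by_system(nc$strengths, atlas, "nope", nc$participants),
               class = "invalid_argument")
})

test_that("symptom correlations match the direct Pearson formula", {
  nc <- make_null_cohort(10, 5, seed = 13)
  nc$participants$hamd <- withr::with_seed(14, rnorm(20, 20, 5))
  res <- correlate_symptoms(nc$strengths, nc$participants, "hamd",
                            case_only = TRUE)
  cases <- nc$participants[nc$participants$group == "case", ]
  for (r in 1:5) {
    s <- nc$strengths[nc$strengths$region_id == r &
                        nc$strengths$subject_id %in% cases$subject_id, ]
    v <- s$strength[match(cases$subject_id, s$subject_id)]
    expect_equal(res$r[res$region_id == r], oracle_pearson(v, cases$hamd),
                 tolerance = 1e-12)
  }
  # scores equal to one region's strengths give r = 1 there
  s1 <- nc$strengths[nc$strengths$region_id == 1, ]
  nc$participants$selfscore <- s1$strength[match(nc$participants$subject_id,
                                                 s1$subject_id)]
  res2 <- correlate_symptoms(nc$strengths, nc$participants, "selfscore",
                             case_only = FALSE)
  expect_equal(res2$r[res2$region_id == 1], 1)
  nc$participants$flat <- 1
  expect_error(correlate_symptoms(nc$strengths, nc$participants, "flat"),
               class = "degenerate_input")
})

test_that("map concordance returns r = 1 / -1 for identical / negated maps", {
  atlas <- tiny_atlas(10)
  spins <- generate_spins(atlas, 99, seed = 4, "both_mirrored")
  a <- withr::with_seed(5, rnorm(20))
  names(a) <- atlas$region_id
  expect_equal(map_concordance(a, a, spins)$r, 1)
  expect_equal(map_concordance(a, -a, spins)$r, -1)
  expect_error(map_concordance(a[1:5], a, spins), class = "invalid_argument")
})
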