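#' Ground truth for a simulation scenario
#'
#' Fixes, up front, everything the generators plant: which regions carry a
#' case-control effect and with which sign, which genes track the effect map
#' and with which signed loading, the standardized effect size, and the seed
#' that governs every stochastic draw. Downstream parameter-recovery tests
#' compare pipeline output against this object.
#'
#' Per-gene planted loadings are drawn here (signed, magnitudes uniform on
#' [0.5, 1.5]) so that the expression generator and the differential-expression
#' generator share one consistent notion of how strongly each planted gene
#' tracks the effect map.
#'
#' @param atlas a `parcel_atlas`.
#' @param effect_regions integer region_ids carrying the planted group effect.
#' @param effect_direction +1/-1 per effect region (recycled if length 1).
#' @param planted_genes character gene symbols with a planted expression signal.
#' @param planted_sign +1/-1 per planted gene (recycled if length 1).
#' @param effect_size standardized latent mean shift in effect regions
#'   (in units of the cohort noise SD).
#' @param seed master integer seed.
#' @return list of class `simulation_truth`.
#' @export
simulation_truth <- function(atlas, effect_regions = integer(), effect_direction = 1,
                             planted_genes = character(), planted_sign = 1,
                             effect_size = 0, seed = 1) {
  effect_regions <- as.integer(effect_regions)
  if (length(effect_regions) && !all(effect_regions %in% atlas$region_id)) {
    stop_msntx("`effect_regions` must all be atlas region_ids.", "invalid_argument")
  }
  effect_direction <- rep_len(sign(effect_direction), length(effect_regions))
  planted_sign <- rep_len(sign(planted_sign), length(planted_genes))
  loading <- withr::with_seed(derive_seed(seed, 11L), {
    planted_sign * runif(length(planted_genes), 0.5, 1.5)
  })
  structure(
    list(
      effect_regions = effect_regions,
      effect_direction = effect_direction,
      planted_genes = as.character(planted_genes),
      planted_sign = planted_sign,
      planted_loading = setNames(loading, planted_genes),
      effect_size = effect_size,
      seed = as.integer(seed)
    ),
    class = "simulation_truth"
  )
}

#' Simulate a case-control cohort of regional morphometric features
#'
#' Generates per-subject region x feature matrices with a known planted group
#' effect, plus a participant covariate table. Each region carries a latent
#' alignment `rho[r, s]` in (-1, 1) with a shared "hub" feature-profile
#' direction `u`; its feature vector is
#'
#'   M[s][r, f] = rho[r, s] * u[f]
#'               + sqrt(1 - rho^2) * idio_sd * w[r, f]  + noise_sd * eps
#'
#' where `w` is a fixed idiosyncratic profile texture shared by all subjects
#' (individual morphometric profiles are largely stable across people) and
#' `eps` is per-subject measurement noise. The between-region Pearson
#' correlation is then approximately `rho_i * rho_j`, so a region's MSN
#' strength increases monotonically with its alignment and `noise_sd` sets
#' the between-subject variability. The baseline alignment is a smooth
#' spatial field
#' (spatially autocorrelated over centroid geodesic distance), so strength
#' maps are smooth. The group effect is planted by shifting the Fisher-z
#' alignment of effect regions for case subjects by
#' `effect_size * noise_sd * direction` — a latent feature-profile rotation
#' whose strength consequence is emergent and sign-controlled rather than a
#' direct shift of strengths. Covariates (age, sex, education) act the same
#' way through their own smooth regional maps.
#'
#' @param atlas a `parcel_atlas`.
#' @param n_per_group subjects per group.
#' @param n_features number of morphometric features (>= 3; default 7,
#'   emulating surface area, thickness, volume, two curvatures, FA and MD).
#' @param truth a `simulation_truth`.
#' @param covariate_spec named list of standardized covariate effect sizes on
#'   the latent alignment, e.g. `list(age = 0.1, sex = 0.1, education = 0.1)`.
#' @param noise_sd feature measurement noise SD; also the unit of the planted
#'   latent shift.
#' @param smoothness spatial kernel length-scale (radians) of the shared maps.
#' @param idio_sd scale of each region's idiosyncratic profile component.
#' @param align_mean,align_sd mean and spatial SD of the baseline Fisher-z
#'   alignment field.
#' @return list with `features` (tibble: subject_id, region_id, f1..fK) and
#'   `participants` (tibble: subject_id, group, age, sex, education, tiv,
#'   hamd, hama).
#' @export
simulate_cohort <- function(atlas, n_per_group, n_features = 7, truth,
                            covariate_spec = list(age = 0, sex = 0, education = 0),
                            noise_sd = 0.2, smoothness = 0.6,
                            idio_sd = 0.5, align_mean = 0.6, align_sd = 0.5) {
  n_per_group <- check_positive_int(n_per_group, "n_per_group")
  n_features <- check_positive_int(n_features, "n_features")
  if (n_features < 3) stop_msntx("`n_features` must be >= 3.", "invalid_argument")
  if (noise_sd <= 0) stop_msntx("`noise_sd` must be positive.", "invalid_argument")
  if (!inherits(truth, "simulation_truth")) {
    stop_msntx("`truth` must be a simulation_truth object.", "invalid_argument")
  }

  cent <- atlas_centroids(atlas)
  nr <- nrow(cent)
  seed <- truth$seed

  # shared structure: hub direction and baseline Fisher-z alignment field
  u <- withr::with_seed(derive_seed(seed, 21L), rnorm(n_features))
  u <- u / sqrt(sum(u^2))
  f0 <- sample_smooth_fields(cent, 1, smoothness, derive_seed(seed, 22L))[, 1]
  # centre the field so `align_mean` really is the mean alignment: smooth
  # fields on the sphere have few effective degrees of freedom and their
  # spatial mean would otherwise swamp it
  z0 <- align_mean + align_sd * (f0 - mean(f0))
  w_tex <- withr::with_seed(derive_seed(seed, 23L),
                            matrix(rnorm(nr * n_features), nr, n_features))

  cov_names <- names(covariate_spec)
  cov_maps <- if (length(cov_names)) {
    sample_smooth_fields(cent, length(cov_names), smoothness, derive_seed(seed, 24L))
  } else {
    matrix(0, nr, 0)
  }

  n_sub <- 2L * n_per_group
  parts <- withr::with_seed(derive_seed(seed, 25L), {
    grp <- rep(c("case", "control"), each = n_per_group)
    tibble::tibble(
      subject_id = sprintf("sub-%03d", seq_len(n_sub)),
      group = grp,
      age = round(rnorm(n_sub, 35, 10), 1),
      sex = rbinom(n_sub, 1, 0.5),
      education = round(rnorm(n_sub, 12, 3), 1),
      tiv = round(rnorm(n_sub, 1.4e6, 1e5)),
      hamd = ifelse(grp == "case", pmax(8, round(rnorm(n_sub, 22, 4))),
                    pmax(0, round(rnorm(n_sub, 2, 1)))),
      hama = ifelse(grp == "case", pmax(0, round(rnorm(n_sub, 18, 4))),
                    pmax(0, round(rnorm(n_sub, 2, 1))))
    )
  })

  d_z_effect <- numeric(nr)
  if (length(truth$effect_regions)) {
    idx <- match(truth$effect_regions, atlas$region_id)
    d_z_effect[idx] <- truth$effect_direction * truth$effect_size * noise_sd
  }

  cov_std <- sapply(cov_names, function(cn) {
    v <- parts[[cn]]
    if (sd(v) == 0) rep(0, n_sub) else (v - mean(v)) / sd(v)
  })
  if (length(cov_names)) cov_std <- matrix(cov_std, nrow = n_sub)

  feats <- withr::with_seed(derive_seed(seed, 26L), {
    purrr::map(seq_len(n_sub), function(s) {
      z_s <- z0
      if (parts$group[s] == "case") z_s <- z_s + d_z_effect
      if (length(cov_names)) {
        beta <- unlist(covariate_spec)
        z_s <- z_s + cov_maps %*% (beta * cov_std[s, ]) * noise_sd
      }
      rho <- tanh(as.numeric(z_s))
      m <- outer(rho, u) +
        sqrt(pmax(0, 1 - rho^2)) * idio_sd * w_tex +
        noise_sd * matrix(rnorm(nr * n_features), nr, n_features)
      colnames(m) <- paste0("f", seq_len(n_features))
      dplyr::bind_cols(
        tibble::tibble(subject_id = parts$subject_id[s], region_id = atlas$region_id),
        tibble::as_tibble(m)
      )
    })
  })
  list(features = dplyr::bind_rows(feats), participants = parts)
}

#' Write cohort tables to disk
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$features, file.path(dir, "features.tsv"))
  readr::write_tsv(cohort$participants, file.path(dir, "participants.tsv"))
  invisible(dir)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir directory containing features.tsv and participants.tsv.
#' @return list with `features` and `participants` tibbles.
#' @export
read_cohort <- function(dir) {
  list(
    features = readr::read_tsv(file.path(dir, "features.tsv"), show_col_types = FALSE),
    participants = readr::read_tsv(file.path(dir, "participants.tsv"), show_col_types = FALSE)
  )
}
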