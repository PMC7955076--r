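#' Demo and strong-signal pipeline configurations
#'
#' `demo_config()` is a small configuration that exercises every stage in
#' well under a minute; `strong_signal_config()` is the documented
#' strong-signal scenario used for parameter-recovery checks (60+60
#' subjects over 154 parcels per hemisphere, 2000 genes with 5% planted,
#' 999 spins, 1000 bootstrap replicates).
#'
#' @param seed master seed; every stage seed is derived from it.
#' @return named list understood by [run_pipeline()].
#' @export
demo_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    atlas = list(n_per_hemisphere = 40, n_systems = 7),
    truth = list(n_effect = 10, effect_size = 3),
    cohort = list(n_per_group = 24, n_features = 7, noise_sd = 0.2,
                  covariate_spec = list(age = 0.1, sex = 0.1, education = 0.1)),
    msn = list(density = 1, mode = "signed"),
    tmap = list(covariates = c("age", "sex", "education")),
    expression = list(n_genes = 400, n_planted = 40, probes_per_gene = 2,
                      n_donors = 4, samples_per_donor = 120,
                      signal_strength = 3, coverage = "complete"),
    prep = list(min_fraction = 0.5, max_distance = 2, left_only = TRUE,
                ds_mode = "top_fraction", ds_threshold = 0.9),
    spins = list(n_spins = 199),
    pls = list(n_boot = 200, z_threshold = 5, fdr_threshold = 0.005,
               scale_x = TRUE),
    dge = list(n_background = 300, corr_strength = 0.8),
    cellsets = list(n_classes = 7, class_sizes = 40,
                    enrichment = c(0.5, 0, 0.3, 0.3, 0, 0, 0))
  )
}

#' @rdname demo_config
#' @export
strong_signal_config <- function(seed = 1) {
  cfg <- demo_config(seed)
  cfg$atlas$n_per_hemisphere <- 154
  cfg$truth$n_effect <- 16
  cfg$truth$effect_size <- 4
  cfg$cohort$n_per_group <- 60
  cfg$expression <- list(n_genes = 2000, n_planted = 100, probes_per_gene = 2,
                         n_donors = 6, samples_per_donor = 400,
                         signal_strength = 4, coverage = "complete")
  cfg$spins$n_spins <- 999
  cfg$pls$n_boot <- 1000
  cfg$dge$n_background <- 1000
  cfg$cellsets$class_sizes <- 100
  cfg
}

# Internal: pick two mirrored contiguous patches of effect regions (one per
# sign) around deterministic anchor parcels.
plant_effect_regions <- function(atlas, n_effect) {
  left <- atlas[atlas$hemisphere == "L", ]
  cl <- atlas_centroids(left)
  d <- greatcircle_dist(cl)
  n_pos <- ceiling(n_effect / 2)
  n_neg <- n_effect - n_pos
  anchor_pos <- 1L
  anchor_neg <- which.max(d[anchor_pos, ])
  pos <- left$region_id[order(d[anchor_pos, ])][seq_len(n_pos)]
  neg <- setdiff(left$region_id[order(d[anchor_neg, ])], pos)[seq_len(n_neg)]
  # mirror to the right hemisphere: same lattice order by construction
  n_l <- nrow(left)
  mirror <- function(ids) ids + n_l
  list(
    regions = c(pos, neg, mirror(pos), mirror(neg)),
    direction = rep(c(1, -1, 1, -1), c(n_pos, n_neg, n_pos, n_neg)),
    left_regions = c(pos, neg),
    left_direction = rep(c(1, -1), c(n_pos, n_neg))
  )
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, in order: atlas and truth construction, cohort simulation, MSN
#' strengths, the case-control t-map (plus quadrant classification, system
#' aggregation and map concordance), expression-bundle simulation and
#' preprocessing, PLS1 with spin test and bootstrap gene Z-scores, gene-list
#' extraction, and the downstream gene-list statistics (DGE correlation,
#' cell-type overlaps, cell-type expression maps). Reruns with an identical
#' configuration are bit-identical.
#'
#' @param config configuration list (see [demo_config()]) or path to a YAML
#'   file holding one.
#' @param out_dir optional output directory; when given, every stage output
#'   is written there along with `manifest.json`.
#' @return named list with all stage results (invisible `out_dir` entries
#'   point at written files when `out_dir` is set).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) {
    stop_msntx("config must carry an explicit `seed`.", "invalid_argument")
  }
  seed <- as.integer(config$seed)

  atlas <- make_atlas(config$atlas$n_per_hemisphere, config$atlas$n_systems, seed)
  planted_genes <- sprintf("planted_%04d", seq_len(config$expression$n_planted))
  eff <- plant_effect_regions(atlas, config$truth$n_effect)
  truth <- simulation_truth(
    atlas,
    effect_regions = eff$regions, effect_direction = eff$direction,
    planted_genes = planted_genes,
    planted_sign = rep_len(c(1, -1), length(planted_genes)),
    effect_size = config$truth$effect_size, seed = seed
  )

  cohort <- simulate_cohort(
    atlas, config$cohort$n_per_group, config$cohort$n_features, truth,
    covariate_spec = config$cohort$covariate_spec,
    noise_sd = config$cohort$noise_sd
  )

  strengths <- compute_strengths(cohort$features, config$msn$density,
                                 config$msn$mode)
  tmap <- fit_tmap(strengths, cohort$participants, config$tmap$covariates)

  control_mean <- strengths |>
    dplyr::inner_join(cohort$participants[, c("subject_id", "group")],
                      by = "subject_id") |>
    dplyr::filter(.data$group == "control") |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(strength = mean(.data$strength), .groups = "drop")
  quadrants <- classify_regions(tmap, control_mean)
  systems <- aggregate_by_system(strengths, atlas, "yeo7",
                                 cohort$participants, config$tmap$covariates)

  spins_all <- generate_spins(atlas, config$spins$n_spins,
                              derive_seed(seed, 61L), "both_mirrored")
  concordance <- map_concordance(
    setNames(tmap$t, tmap$region_id),
    setNames(control_mean$strength, control_mean$region_id),
    spins_all
  )

  # expression: planted genes track the planted effect map, smoothed by the
  # spatial kernel the way a regional perturbation propagates through the
  # similarity structure
  left <- atlas[atlas$hemisphere == "L", ]
  left_ids <- left$region_id
  signal_map <- setNames(numeric(length(left_ids)), left_ids)
  signal_map[as.character(eff$left_regions)] <- eff$left_direction
  map_ls <- config$truth$map_smoothness
  if (is.null(map_ls)) map_ls <- 0.15
  kd <- exp(-greatcircle_dist(atlas_centroids(left))^2 / (2 * map_ls^2))
  signal_map <- setNames(as.numeric(kd %*% signal_map), left_ids)
  bundle <- rlang::exec(simulate_expression_bundle,
                        atlas = atlas, signal_map = signal_map, truth = truth,
                        !!!config$expression[setdiff(names(config$expression),
                                                     "n_planted")])
  rgm <- build_region_gene_matrix(bundle, atlas, config$prep)

  y_left <- setNames(tmap$t, tmap$region_id)
  y_left <- y_left[rownames(rgm$values)]
  sub_atlas <- atlas[atlas$region_id %in% as.integer(rownames(rgm$values)), ]
  spins_left <- generate_spins(sub_atlas, config$spins$n_spins,
                               derive_seed(seed, 62L), "left_only")

  pls <- fit_pls1(rgm, y_left, scale_x = config$pls$scale_x)
  spin_res <- pls_spin_test(rgm, y_left, spins_left, config$pls$scale_x)
  ztable <- bootstrap_gene_weights(rgm, y_left, config$pls$n_boot,
                                   derive_seed(seed, 63L), config$pls$scale_x)
  lists <- extract_gene_lists(ztable, config$pls$z_threshold,
                              config$pls$fdr_threshold)

  dge <- simulate_dge_table(truth, config$dge$n_background,
                            config$dge$corr_strength)
  gene_universe <- colnames(rgm$values)
  minus_weights <- ztable[ztable$gene %in% lists$pls1_minus, ]
  dge_stats <- if (nrow(minus_weights) >= 3) {
    tryCatch(dge_spearman_test(minus_weights, dge, "up",
                               n_perm = config$spins$n_spins,
                               seed = derive_seed(seed, 64L)),
             error = function(e) NULL)
  }

  cell_cfg <- config$cellsets
  cell_cfg$class_sizes <- pmin(cell_cfg$class_sizes, length(gene_universe))
  cells <- rlang::exec(make_cell_sets,
                       gene_universe = gene_universe,
                       planted_genes = truth$planted_genes,
                       seed = derive_seed(seed, 65L),
                       !!!cell_cfg)
  overlap_stats <- celltype_overlap_test(lists$pls1_minus, cells, gene_universe,
                                         n_perm = config$spins$n_spins,
                                         seed = derive_seed(seed, 66L))
  cell_maps <- suppressMessages(
    celltype_expression_maps(rgm, lists$pls1_minus, cells)
  )

  results <- list(
    config = config, atlas = atlas, truth = truth, cohort = cohort,
    strengths = strengths, tmap = tmap, control_mean = control_mean,
    quadrants = quadrants, systems = systems, concordance = concordance,
    bundle = bundle, region_gene = rgm, pls = pls, spin = spin_res,
    ztable = ztable, gene_lists = lists, dge = dge, dge_stats = dge_stats,
    cell_sets = cells, overlap_stats = overlap_stats, cell_maps = cell_maps
  )
  if (!is.null(out_dir)) write_pipeline_outputs(results, out_dir)
  results
}

# Internal: serialize every stage output plus a manifest.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_atlas(res$atlas, p("atlas.tsv"))
  writeLines(jsonlite::toJSON(res$truth[c("effect_regions", "effect_direction",
                                          "planted_genes", "planted_sign",
                                          "effect_size", "seed")],
                              auto_unbox = TRUE, digits = NA), p("truth.json"))
  write_cohort(res$cohort, out_dir)
  readr::write_tsv(res$strengths, p("msn_strength.tsv"))
  readr::write_tsv(tibble::as_tibble(res$tmap), p("tmap.tsv"))
  readr::write_tsv(tibble::as_tibble(res$quadrants), p("quadrants.tsv"))
  readr::write_tsv(tibble::as_tibble(res$systems), p("systems.tsv"))
  writeLines(jsonlite::toJSON(as.list(res$concordance), auto_unbox = TRUE,
                              digits = NA), p("concordance.json"))
  write_region_gene_matrix(res$region_gene, out_dir)
  write_association(
    res$ztable, res$gene_lists,
    list(var_explained = res$pls$var_explained, p_spin = res$spin$p_spin,
         n_boot = attr(res$ztable, "n_boot"), seed = res$config$seed),
    out_dir
  )
  if (!is.null(res$dge_stats)) readr::write_tsv(res$dge_stats, p("dge_stats.tsv"))
  readr::write_tsv(res$overlap_stats, p("overlap_stats.tsv"))
  readr::write_tsv(res$cell_maps, p("celltype_maps.tsv"))
  manifest <- list(
    package = "msntx",
    version = as.character(utils::packageVersion("msntx")),
    config = res$config,
    config_hash = rlang::hash(res$config),
    provenance = res$region_gene$provenance
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), p("manifest.json"))
  invisible(out_dir)
}

#' Validate pipeline input files
#'
#' Schema and consistency checks for on-disk inputs: the feature table, the
#' participant table, the atlas, and (optionally) an expression bundle
#' directory in the AHBA CSV dialect. Returns a machine-readable report of
#' failures; an empty report means everything checked out.
#'
#' @param paths named list with any of `features`, `participants`, `atlas`,
#'   `bundle_dir`.
#' @return tibble (input, check, message), one row per failure.
#' @export
validate_inputs <- function(paths) {
  fails <- list()
  add <- function(input, check, message) {
    fails[[length(fails) + 1]] <<- tibble::tibble(
      input = input, check = check, message = message)
  }
  atlas <- NULL
  if (!is.null(paths$atlas)) {
    if (!file.exists(paths$atlas)) {
      add("atlas", "exists", "file not found")
    } else {
      atlas <- readr::read_tsv(paths$atlas, show_col_types = FALSE)
      need <- c("region_id", "hemisphere", "cx", "cy", "cz")
      miss <- setdiff(need, names(atlas))
      if (length(miss)) add("atlas", "columns", paste("missing:", paste(miss, collapse = ", ")))
      if (!length(miss)) {
        if (anyDuplicated(atlas$region_id)) add("atlas", "region_id", "duplicate region_ids")
        if (!all(c("L", "R") %in% atlas$hemisphere)) {
          add("atlas", "hemispheres", "both hemispheres must be non-empty")
        }
        nrm <- sqrt(atlas$cx^2 + atlas$cy^2 + atlas$cz^2)
        if (any(abs(nrm - 1) > 1e-6)) add("atlas", "centroids", "centroids not unit norm")
      }
    }
  }
  if (!is.null(paths$features)) {
    if (!file.exists(paths$features)) {
      add("features", "exists", "file not found")
    } else {
      ft <- readr::read_tsv(paths$features, show_col_types = FALSE)
      need <- c("subject_id", "region_id")
      miss <- setdiff(need, names(ft))
      if (length(miss)) add("features", "columns", paste("missing:", paste(miss, collapse = ", ")))
      if (!length(miss)) {
        if (anyNA(ft)) add("features", "missing_values", "table contains NAs")
        counts <- table(ft$subject_id)
        if (length(unique(counts)) > 1) {
          add("features", "region_coverage", "subjects cover differing region sets")
        }
        if (!is.null(atlas) &&
            !setequal(unique(ft$region_id), atlas$region_id)) {
          add("features", "atlas_match", "feature regions do not match the atlas")
        }
      }
    }
  }
  if (!is.null(paths$participants)) {
    if (!file.exists(paths$participants)) {
      add("participants", "exists", "file not found")
    } else {
      pp <- readr::read_tsv(paths$participants, show_col_types = FALSE)
      miss <- setdiff(c("subject_id", "group"), names(pp))
      if (length(miss)) add("participants", "columns", paste("missing:", paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(paths$bundle_dir)) {
    donor_dirs <- list.dirs(paths$bundle_dir, recursive = FALSE)
    if (!length(donor_dirs)) {
      add("bundle", "donors", "no donor directories found")
    }
    for (dd in donor_dirs) {
      for (f in c("MicroarrayExpression.csv", "SampleAnnot.csv", "PACall.csv")) {
        if (!file.exists(file.path(dd, f))) {
          add("bundle", "files", sprintf("%s missing %s", basename(dd), f))
        }
      }
      ef <- file.path(dd, "MicroarrayExpression.csv")
      pf <- file.path(dd, "PACall.csv")
      if (file.exists(ef) && file.exists(pf)) {
        e1 <- readr::read_csv(ef, col_names = FALSE, show_col_types = FALSE,
                              n_max = 1)
        nle <- length(readr::read_lines(ef))
        p1 <- readr::read_csv(pf, col_names = FALSE, show_col_types = FALSE,
                              n_max = 1)
        nlp <- length(readr::read_lines(pf))
        if (ncol(e1) != ncol(p1) || nle != nlp) {
          add("bundle", "pacall_shape",
              sprintf("%s: PACall shape does not match expression", basename(dd)))
        }
      }
    }
  }
  if (!length(fails)) {
    return(tibble::tibble(input = character(), check = character(),
                          message = character()))
  }
  dplyr::bind_rows(fails)
}
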