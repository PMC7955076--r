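#' Simulate a multi-donor, multi-probe expression bundle
#'
#' Emulates the file-level structure of the Allen Human Brain Atlas microarray
#' release: per-donor probe x sample intensity matrices on a log2-like scale,
#' sample annotations with 3D coordinates, probe-to-gene annotations, and
#' binary present/absent detection calls, plus an RNA-seq-like gene x region
#' reference used for probe selection.
#'
#' Each gene's regional profile is a smooth random field (squared-exponential
#' kernel on centroid geodesic distance, length-scale `smoothness`); planted
#' genes additionally receive `signal_strength * loading * scale(signal_map)`
#' on the left hemisphere, where loadings come from the `simulation_truth`.
#' Exactly one probe per gene (the first) is generated with highest fidelity
#' to its gene's profile; extra probes mix in a decoy gene's profile and
#' carry probe-specific bias and noise. A configurable fraction of extra
#' probes is generated at very low intensity (absent in most samples, to
#' exercise the intensity filter) or with broken annotations (missing or
#' ambiguous in the re-annotation mapping). Samples sit at donor-jittered
#' positions near parcel representative points (`radius` * centroid); small
#' fractions are placed in the right hemisphere or beyond the assignment
#' distance to exercise those filters. Calls are absent where intensity falls
#' below the donor-specific `background_quantile` quantile.
#'
#' @param atlas a `parcel_atlas`.
#' @param n_genes gene universe size (planted genes included in the count).
#' @param probes_per_gene probes generated per gene.
#' @param n_donors number of donors (>= 2; differential stability needs pairs).
#' @param samples_per_donor tissue samples per donor.
#' @param signal_map named numeric vector indexed by left-hemisphere
#'   region_ids; the spatial map planted genes track.
#' @param truth a `simulation_truth` carrying planted genes and loadings.
#' @param smoothness spatial kernel length-scale in radians.
#' @param signal_strength multiplier on planted loadings (expression units per
#'   SD of the signal map).
#' @param profile_sd SD of the smooth baseline component of gene profiles.
#' @param probe_noise_sd measurement noise SD for extra probes; the
#'   high-fidelity probe uses a fifth of it.
#' @param probe_bias_sd SD of probe-specific additive bias (extra probes only).
#' @param decoy_mix fraction of a decoy gene profile mixed into extra probes.
#' @param jitter_sd SD of the isotropic spatial jitter on sample positions,
#'   in the same units as `radius`.
#' @param radius scale from unit-sphere centroids to the sample coordinate
#'   frame (a stand-in for mm).
#' @param right_frac fraction of samples drawn from right-hemisphere regions.
#' @param far_frac fraction of samples pushed beyond the assignment distance.
#' @param low_probe_frac fraction of extra probes generated near background.
#' @param bad_annotation_frac fraction of extra probes with broken annotations.
#' @param background_quantile donor-level intensity quantile below which calls
#'   are absent; 0 marks everything present.
#' @param coverage "random" places samples at uniformly drawn left regions;
#'   "complete" guarantees every left region at least one sample per donor.
#' @param ref_noise_sd noise SD of the RNA-seq-like reference.
#' @param seed integer seed; defaults to the truth's seed.
#' @return list of class `expression_bundle`; see Details. `meta` carries
#'   generator bookkeeping (true profiles, best probe per gene, planted-bad
#'   probe ids) for parameter-recovery tests.
#' @export
simulate_expression_bundle <- function(atlas, n_genes, probes_per_gene = 2,
                                       n_donors = 6, samples_per_donor = 100,
                                       signal_map, truth,
                                       smoothness = 0.5, signal_strength = 2,
                                       profile_sd = 1.5, probe_noise_sd = 0.3,
                                       probe_bias_sd = 0.5, decoy_mix = 0.4,
                                       jitter_sd = 0.5, radius = 75,
                                       right_frac = 0.05, far_frac = 0.05,
                                       low_probe_frac = 0.1,
                                       bad_annotation_frac = 0.1,
                                       background_quantile = 0.2,
                                       coverage = c("random", "complete"),
                                       ref_noise_sd = 0.1, seed = NULL) {
  n_genes <- check_positive_int(n_genes, "n_genes")
  probes_per_gene <- check_positive_int(probes_per_gene, "probes_per_gene")
  if (n_donors < 2) stop_msntx("`n_donors` must be >= 2.", "invalid_argument")
  n_donors <- check_positive_int(n_donors, "n_donors")
  coverage <- match.arg(coverage)
  if (is.null(seed)) seed <- truth$seed

  left_ids <- atlas$region_id[atlas$hemisphere == "L"]
  right_ids <- atlas$region_id[atlas$hemisphere == "R"]
  if (is.null(names(signal_map)) ||
      !all(names(signal_map) %in% as.character(left_ids)) ||
      length(signal_map) != length(left_ids)) {
    stop_msntx("`signal_map` must be named by all left-hemisphere region_ids.",
               "invalid_argument")
  }
  signal_map <- signal_map[as.character(left_ids)]

  planted <- truth$planted_genes
  if (length(planted) > n_genes) {
    stop_msntx("`n_genes` smaller than the planted gene set.", "invalid_argument")
  }
  genes <- c(planted, sprintf("gene_%05d", seq_len(n_genes - length(planted))))

  cent <- atlas_centroids(atlas)
  nr <- nrow(cent)

  # true regional profiles: smooth field + planted signal (left hemisphere)
  profiles <- 7 +
    profile_sd * sample_smooth_fields(cent, n_genes, smoothness, derive_seed(seed, 31L))
  colnames(profiles) <- genes
  rownames(profiles) <- atlas$region_id
  sm_std <- if (sd(signal_map) > 0) {
    (signal_map - mean(signal_map)) / sd(signal_map)
  } else {
    signal_map * 0
  }
  li <- match(left_ids, atlas$region_id)
  for (g in planted) {
    profiles[li, g] <- profiles[li, g] +
      signal_strength * truth$planted_loading[[g]] * sm_std
  }

  # probe table: first probe per gene is the high-fidelity one
  probe_id <- 10000L + seq_len(n_genes * probes_per_gene)
  probes <- tibble::tibble(
    probe_id = probe_id,
    gene_symbol = rep(genes, each = probes_per_gene),
    rank_in_gene = rep(seq_len(probes_per_gene), times = n_genes)
  )
  extra <- which(probes$rank_in_gene > 1L)
  bundle_meta <- withr::with_seed(derive_seed(seed, 32L), {
    low <- sort(sample(extra, round(low_probe_frac * length(extra))))
    bad_pool <- setdiff(extra, low)
    bad <- sort(sample(bad_pool, round(bad_annotation_frac * length(extra))))
    bias <- numeric(nrow(probes))
    bias[extra] <- rnorm(length(extra), 0, probe_bias_sd)
    decoy <- rep(NA_integer_, nrow(probes))
    decoy[extra] <- sample(n_genes, length(extra), replace = TRUE)
    list(low_probes = probes$probe_id[low], bad_probes = probes$probe_id[bad],
         bias = bias, decoy = decoy)
  })

  # re-annotation mapping: drop "bad" probes or make them ambiguous
  mapping <- probes[, c("probe_id", "gene_symbol")]
  if (length(bundle_meta$bad_probes)) {
    bad <- bundle_meta$bad_probes
    half <- bad[seq_len(floor(length(bad) / 2))]
    mapping <- mapping[!(mapping$probe_id %in% half), ]  # missing annotation
    amb <- setdiff(bad, half)                            # ambiguous annotation
    if (length(amb)) {
      mapping <- dplyr::bind_rows(
        mapping,
        tibble::tibble(probe_id = amb, gene_symbol = "AMBIG_ALT")
      )
    }
  }

  rep_points <- radius * cent

  donors <- withr::with_seed(derive_seed(seed, 33L), {
    setNames(purrr::map(seq_len(n_donors), function(d) {
      ns <- samples_per_donor
      reg <- if (coverage == "complete") {
        c(left_ids, sample(left_ids, max(0, ns - length(left_ids)), replace = TRUE))
      } else {
        sample(left_ids, ns, replace = TRUE)
      }
      ns <- length(reg)
      n_right <- round(right_frac * ns)
      if (n_right > 0 && length(right_ids)) {
        reg[sample(ns, n_right)] <- sample(right_ids, n_right, replace = TRUE)
      }
      far <- rep(FALSE, ns)
      n_far <- round(far_frac * ns)
      if (n_far > 0) far[sample(ns, n_far)] <- TRUE

      ri <- match(reg, atlas$region_id)
      pos <- rep_points[ri, , drop = FALSE] +
        matrix(rnorm(ns * 3, 0, jitter_sd), ns, 3)
      if (any(far)) {
        push <- (3 + stats::rexp(sum(far), 1))
        pos[far, ] <- rep_points[ri[far], , drop = FALSE] * (1 + push / radius)
      }
      donor_shift <- rnorm(1, 0, 0.5)

      expr <- matrix(0, nrow(probes), ns)
      base <- t(profiles[ri, , drop = FALSE])          # genes x samples
      gi <- match(probes$gene_symbol, genes)
      hi <- probes$rank_in_gene == 1L
      expr[hi, ] <- base[gi[hi], , drop = FALSE] +
        matrix(rnorm(sum(hi) * ns, 0, probe_noise_sd / 5), sum(hi), ns)
      if (any(!hi)) {
        dec <- bundle_meta$decoy[!hi]
        expr[!hi, ] <- (1 - decoy_mix) * base[gi[!hi], , drop = FALSE] +
          decoy_mix * base[dec, , drop = FALSE] +
          bundle_meta$bias[!hi] +
          matrix(rnorm(sum(!hi) * ns, 0, probe_noise_sd), sum(!hi), ns)
      }
      low_idx <- match(bundle_meta$low_probes, probes$probe_id)
      if (length(low_idx)) expr[low_idx, ] <- expr[low_idx, ] - 12
      expr <- expr + donor_shift
      rownames(expr) <- probes$probe_id

      samp <- tibble::tibble(
        sample_id = sprintf("D%02d_S%04d", d, seq_len(ns)),
        donor_id = sprintf("donor_%02d", d),
        mni_x = pos[, 1], mni_y = pos[, 2], mni_z = pos[, 3],
        structure_id = reg
      )
      colnames(expr) <- samp$sample_id

      pacall <- if (background_quantile > 0) {
        (expr >= quantile(expr, background_quantile)) * 1L
      } else {
        matrix(1L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
      }
      list(expression = expr, samples = samp, pacall = pacall)
    }), sprintf("donor_%02d", seq_len(n_donors)))
  })

  reference <- withr::with_seed(derive_seed(seed, 34L), {
    t(profiles[li, , drop = FALSE]) +
      matrix(rnorm(n_genes * length(li), 0, ref_noise_sd), n_genes, length(li))
  })
  rownames(reference) <- genes
  colnames(reference) <- left_ids

  structure(
    list(
      donors = donors,
      probes = probes[, c("probe_id", "gene_symbol")],
      probe_mapping = mapping,
      reference = reference,
      radius = radius,
      meta = list(
        genes = genes,
        profiles = profiles,
        best_probe = setNames(probes$probe_id[probes$rank_in_gene == 1L], genes),
        low_probes = bundle_meta$low_probes,
        bad_probes = bundle_meta$bad_probes,
        left_ids = left_ids,
        seed = seed
      )
    ),
    class = "expression_bundle"
  )
}

#' Write / read an expression bundle in the AHBA CSV dialect
#'
#' One directory per donor containing `MicroarrayExpression.csv` (first column
#' probe_id, no header, one column per sample), `SampleAnnot.csv`,
#' `Probes.csv` and `PACall.csv` (same shape as the expression file), plus
#' top-level `Probes.csv`, `probe_mapping.csv` and `reference_expression.csv`.
#'
#' @param bundle an `expression_bundle`.
#' @param dir output directory.
#' @return `dir` invisibly (writer); an `expression_bundle` without generator
#'   metadata (reader).
#' @export
write_bundle_csvs <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (dn in names(bundle$donors)) {
    dd <- file.path(dir, dn)
    dir.create(dd, showWarnings = FALSE)
    don <- bundle$donors[[dn]]
    expr <- data.frame(probe_id = rownames(don$expression), don$expression,
                       check.names = FALSE)
    readr::write_csv(expr, file.path(dd, "MicroarrayExpression.csv"),
                     col_names = FALSE)
    readr::write_csv(don$samples, file.path(dd, "SampleAnnot.csv"))
    pac <- data.frame(probe_id = rownames(don$pacall), don$pacall,
                      check.names = FALSE)
    readr::write_csv(pac, file.path(dd, "PACall.csv"), col_names = FALSE)
    readr::write_csv(bundle$probes, file.path(dd, "Probes.csv"))
  }
  readr::write_csv(bundle$probes, file.path(dir, "Probes.csv"))
  readr::write_csv(bundle$probe_mapping, file.path(dir, "probe_mapping.csv"))
  ref <- data.frame(gene_symbol = rownames(bundle$reference), bundle$reference,
                    check.names = FALSE)
  readr::write_csv(ref, file.path(dir, "reference_expression.csv"))
  writeLines(jsonlite::toJSON(list(radius = bundle$radius), auto_unbox = TRUE),
             file.path(dir, "bundle.json"))
  invisible(dir)
}

#' @rdname write_bundle_csvs
#' @export
read_bundle_csvs <- function(dir) {
  donor_dirs <- list.dirs(dir, recursive = FALSE)
  donors <- setNames(purrr::map(donor_dirs, function(dd) {
    expr <- as.data.frame(readr::read_csv(
      file.path(dd, "MicroarrayExpression.csv"), col_names = FALSE,
      show_col_types = FALSE))
    samp <- readr::read_csv(file.path(dd, "SampleAnnot.csv"), show_col_types = FALSE)
    pac <- as.data.frame(readr::read_csv(
      file.path(dd, "PACall.csv"), col_names = FALSE, show_col_types = FALSE))
    em <- as.matrix(expr[, -1, drop = FALSE])
    pm <- as.matrix(pac[, -1, drop = FALSE])
    dimnames(em) <- list(expr[[1]], samp$sample_id)
    dimnames(pm) <- list(pac[[1]], samp$sample_id)
    list(expression = em, samples = samp, pacall = pm)
  }), basename(donor_dirs))
  probes <- readr::read_csv(file.path(dir, "Probes.csv"), show_col_types = FALSE)
  mapping <- readr::read_csv(file.path(dir, "probe_mapping.csv"), show_col_types = FALSE)
  ref <- as.data.frame(readr::read_csv(file.path(dir, "reference_expression.csv"),
                                       show_col_types = FALSE))
  rm_ <- as.matrix(ref[, -1, drop = FALSE])
  rownames(rm_) <- ref[[1]]
  meta <- jsonlite::fromJSON(file.path(dir, "bundle.json"))
  structure(
    list(donors = donors, probes = probes, probe_mapping = mapping,
         reference = rm_, radius = meta$radius, meta = NULL),
    class = "expression_bundle"
  )
}
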