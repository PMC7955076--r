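#' Re-annotate probes against an external probe-to-gene mapping
#'
#' Keeps a probe only when the mapping assigns it exactly one gene symbol and
#' that symbol does not contradict the bundle's own annotation. Probes
#' missing from the mapping, mapped to multiple symbols, or mapped to a
#' different symbol are dropped.
#'
#' @param probes tibble (probe_id, gene_symbol).
#' @param mapping tibble (probe_id, gene_symbol) from the re-annotation
#'   source.
#' @return filtered probe tibble with a `dropped` attribute giving counts per
#'   reason (missing, ambiguous, contradicted).
#' @export
reannotate_probes <- function(probes, mapping) {
  counts <- mapping |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(n_sym = dplyr::n_distinct(.data$gene_symbol),
                     symbol = dplyr::first(.data$gene_symbol), .groups = "drop")
  m <- match(probes$probe_id, counts$probe_id)
  missing <- is.na(m)
  ambiguous <- !missing & counts$n_sym[m] > 1
  contradicted <- !missing & !ambiguous &
    counts$symbol[m] != probes$gene_symbol
  keep <- !(missing | ambiguous | contradicted)
  out <- probes[keep, ]
  if (!nrow(out)) stop_msntx("re-annotation removed every probe.", "pipeline_halt")
  attr(out, "dropped") <- c(missing = sum(missing), ambiguous = sum(ambiguous),
                            contradicted = sum(contradicted))
  out
}

#' Intensity-based probe filtering from present/absent calls
#'
#' Keeps a probe when its fraction of "present" detection calls, pooled
#' across all donors' samples (or within every donor with
#' `pooling = "per_donor"`), is at least `min_fraction`.
#'
#' @param bundle an `expression_bundle`.
#' @param min_fraction minimum present fraction (default 0.5: a probe must
#'   exceed background in at least half of all samples).
#' @param pooling pool samples across donors (default) or require the
#'   threshold within each donor.
#' @return integer vector of surviving probe_ids with a `present_fraction`
#'   attribute.
#' @export
filter_probes_intensity <- function(bundle, min_fraction = 0.5,
                                    pooling = c("pooled", "per_donor")) {
  pooling <- match.arg(pooling)
  calls <- purrr::map(bundle$donors, "pacall")
  if (pooling == "pooled") {
    present <- Reduce(`+`, purrr::map(calls, rowSums))
    total <- sum(vapply(calls, ncol, integer(1)))
    frac <- present / total
    keep <- frac >= min_fraction
  } else {
    fracs <- vapply(calls, function(m) rowMeans(m), numeric(nrow(calls[[1]])))
    frac <- rowMeans(fracs)
    keep <- apply(fracs >= min_fraction, 1, all)
  }
  ids <- as.integer(rownames(calls[[1]]))
  out <- ids[keep]
  attr(out, "present_fraction") <- setNames(frac, ids)
  out
}

# Internal: per-probe profile averaged over samples grouped by native
# structure label, pooled across donors. Returns probes x structures matrix.
probe_structure_profiles <- function(bundle, probe_ids) {
  pid <- as.character(probe_ids)
  sums <- NULL; cnts <- NULL
  for (don in bundle$donors) {
    expr <- don$expression[pid, , drop = FALSE]
    f <- factor(don$samples$structure_id)
    agg_s <- t(rowsum(t(expr), f))              # probes x structures (sums)
    agg_n <- as.numeric(table(f))
    if (is.null(sums)) {
      sums <- agg_s
      cnts <- matrix(rep(agg_n, each = nrow(agg_s)), nrow(agg_s))
      colnames(cnts) <- colnames(agg_s)
    } else {
      all_str <- union(colnames(sums), colnames(agg_s))
      grow <- function(m, cols) {
        add <- setdiff(cols, colnames(m))
        if (length(add)) {
          m <- cbind(m, matrix(0, nrow(m), length(add),
                               dimnames = list(NULL, add)))
        }
        m[, cols, drop = FALSE]
      }
      sums <- grow(sums, all_str); cnts <- grow(cnts, all_str)
      sums[, colnames(agg_s)] <- sums[, colnames(agg_s)] + agg_s
      cnts[, colnames(agg_s)] <- cnts[, colnames(agg_s)] +
        matrix(rep(agg_n, each = nrow(agg_s)), nrow(agg_s))
    }
  }
  prof <- sums / cnts
  rownames(prof) <- pid
  prof
}

#' Select one probe per gene by fidelity to a reference
#'
#' For each gene, picks the surviving probe whose structure-averaged profile
#' has the highest Spearman correlation with the gene's profile in an
#' RNA-seq-like reference. Genes absent from the reference fall back to the
#' probe with the highest mean intensity. Ties resolve to the lowest
#' probe_id.
#'
#' @param bundle an `expression_bundle`.
#' @param probe_ids surviving probe_ids (from intensity filtering).
#' @param reference gene x region matrix; defaults to the bundle's own
#'   reference.
#' @param method correlation method for the fidelity score.
#' @return tibble (gene_symbol, probe_id, score, rule).
#' @export
select_probes <- function(bundle, probe_ids, reference = bundle$reference,
                          method = "spearman") {
  probes <- bundle$probes[bundle$probes$probe_id %in% probe_ids, ]
  if (!nrow(probes)) stop_msntx("no probes to select from.", "pipeline_halt")
  prof <- probe_structure_profiles(bundle, probes$probe_id)
  mean_int <- rowMeans(prof)
  common_str <- intersect(colnames(prof), colnames(reference))

  sel <- probes |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::group_modify(function(df, key) {
      g <- key$gene_symbol
      pid <- as.character(df$probe_id)
      if (g %in% rownames(reference) && length(common_str) >= 3) {
        ref <- reference[g, common_str]
        score <- vapply(pid, function(p) {
          suppressWarnings(cor(prof[p, common_str], ref, method = method))
        }, numeric(1))
        score[is.na(score)] <- -Inf
        rule <- "reference_correlation"
      } else {
        score <- mean_int[pid]
        rule <- "mean_intensity"
      }
      best <- which(score == max(score))
      best <- best[which.min(df$probe_id[best])]
      tibble::tibble(probe_id = df$probe_id[best], score = score[best],
                     rule = rule)
    }) |>
    dplyr::ungroup()
  sel
}

#' Assign tissue samples to atlas parcels
#'
#' Each sample is assigned to the nearest parcel representative point
#' (`radius * centroid`) if and only if that distance does not exceed
#' `max_distance`; otherwise it stays unassigned. With `left_only = TRUE`
#' (the default, reflecting left-hemisphere-only expression coverage),
#' samples nearest to a right-hemisphere parcel are excluded.
#'
#' @param bundle an `expression_bundle`.
#' @param atlas a `parcel_atlas`.
#' @param max_distance assignment radius in coordinate units (default 2.0).
#' @param left_only drop samples assigned to the right hemisphere.
#' @return tibble (donor_id, sample_id, region_id, distance); `region_id` is
#'   NA for unassigned samples.
#' @export
assign_samples <- function(bundle, atlas, max_distance = 2, left_only = TRUE) {
  rep_points <- bundle$radius * atlas_centroids(atlas)
  out <- purrr::map(bundle$donors, function(don) {
    pos <- as.matrix(don$samples[, c("mni_x", "mni_y", "mni_z")])
    d2 <- outer(rowSums(pos^2), rowSums(rep_points^2), "+") -
      2 * tcrossprod(pos, rep_points)
    j <- max.col(-d2, ties.method = "first")
    dist <- sqrt(pmax(0, d2[cbind(seq_len(nrow(pos)), j)]))
    region <- atlas$region_id[j]
    hemi <- atlas$hemisphere[j]
    region[dist > max_distance] <- NA_integer_
    if (left_only) region[!is.na(region) & hemi == "R"] <- NA_integer_
    tibble::tibble(donor_id = don$samples$donor_id,
                   sample_id = don$samples$sample_id,
                   region_id = region, distance = dist)
  })
  res <- dplyr::bind_rows(out)
  if (all(is.na(res$region_id))) {
    stop_msntx("no samples could be assigned to any parcel.", "pipeline_halt")
  }
  res
}

#' Scaled robust sigmoid normalization
#'
#' Per gene (column): `x' = 1 / (1 + exp(-(x - median(x)) / IQR(x)))`,
#' followed by min-max rescaling to [0, 1]. The median/IQR standardization
#' makes the transform robust to outlying samples; the sigmoid and rescale
#' put every gene on a common [0, 1] scale within each donor. Genes with
#' zero IQR are set to the constant 0.5 and flagged.
#'
#' @param donor_matrix numeric region (or sample) x gene matrix for one donor.
#' @return matrix of the same shape in [0, 1], with a `flagged_genes`
#'   attribute naming zero-IQR columns.
#' @export
srs_normalize <- function(donor_matrix) {
  m <- as.matrix(donor_matrix)
  med <- apply(m, 2, median)
  iqr <- apply(m, 2, stats::IQR)
  flagged <- colnames(m)[iqr == 0]
  out <- m
  for (jj in seq_len(ncol(m))) {
    if (iqr[jj] == 0) {
      out[, jj] <- 0.5
    } else {
      s <- 1 / (1 + exp(-(m[, jj] - med[jj]) / iqr[jj]))
      rng <- range(s)
      out[, jj] <- if (diff(rng) == 0) 0.5 else (s - rng[1]) / diff(rng)
    }
  }
  attr(out, "flagged_genes") <- flagged
  out
}

#' Differential stability across donors
#'
#' A gene's differential stability (DS) is the mean over donor pairs of the
#' Spearman correlation between the two donors' regional expression profiles,
#' restricted to regions both donors cover. High-DS genes have reproducible
#' spatial patterns across brains; filtering on DS removes genes whose
#' regional profile is mostly donor noise.
#'
#' @param donor_mats named list of region x gene matrices (rownames =
#'   region_id), one per donor.
#' @param threshold_mode "top_fraction" keeps the highest-DS fraction of
#'   genes; "ds_min" keeps genes with DS >= threshold.
#' @param threshold fraction (default 0.5) or DS cut-off, per mode.
#' @return list with `genes` (retained symbols) and `ds` (tibble: gene, ds).
#' @export
differential_stability_filter <- function(donor_mats,
                                          threshold_mode = c("top_fraction", "ds_min"),
                                          threshold = 0.5) {
  threshold_mode <- match.arg(threshold_mode)
  if (length(donor_mats) < 2) stop_msntx(">= 2 donors required.", "invalid_argument")
  genes <- colnames(donor_mats[[1]])
  pairs <- utils::combn(length(donor_mats), 2)
  acc <- matrix(0, length(genes), ncol(pairs), dimnames = list(genes, NULL))
  use <- matrix(FALSE, length(genes), ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- donor_mats[[pairs[1, k]]]
    b <- donor_mats[[pairs[2, k]]]
    shared <- intersect(rownames(a), rownames(b))
    if (length(shared) < 3) next
    ra <- apply(a[shared, genes, drop = FALSE], 2, rank)
    rb <- apply(b[shared, genes, drop = FALSE], 2, rank)
    ra <- scale(ra); rb <- scale(rb)
    rho <- colSums(ra * rb) / (length(shared) - 1)
    ok <- is.finite(rho)
    acc[ok, k] <- rho[ok]
    use[, k] <- ok
  }
  npair <- rowSums(use)
  ds <- ifelse(npair > 0, rowSums(acc) / pmax(1, npair), NA_real_)
  ds_tbl <- tibble::tibble(gene = genes, ds = as.numeric(ds))
  keep <- if (threshold_mode == "ds_min") {
    !is.na(ds) & ds >= threshold
  } else {
    !is.na(ds) & rank(-ds, ties.method = "first") <= round(threshold * sum(!is.na(ds)))
  }
  list(genes = genes[keep], ds = ds_tbl)
}

#' Run the full expression preprocessing pipeline
#'
#' Turns a multi-donor probe-level bundle into a left-hemisphere region x
#' gene matrix through the canonical six steps, in fixed order:
#' (i) probe re-annotation, (ii) intensity-based filtering on detection
#' calls, (iii) probe selection against an RNA-seq-like reference,
#' (iv) spatial assignment of samples to parcels, (v) scaled-robust-sigmoid
#' normalization per donor, and (vi) differential-stability gene filtering.
#' Samples retained in a region are averaged within donor, normalized, then
#' averaged across donors.
#'
#' @param bundle an `expression_bundle`.
#' @param atlas a `parcel_atlas`.
#' @param config list of stage parameters: `min_fraction` (0.5),
#'   `intensity_pooling` ("pooled"), `max_distance` (2), `left_only` (TRUE),
#'   `ds_mode` ("top_fraction"), `ds_threshold` (0.5; set `ds_mode = "none"`
#'   to skip), `reannotate` (TRUE; FALSE skips step i when no mapping
#'   exists).
#' @return object of class `region_gene_matrix`: list with `values`
#'   (region x gene matrix in [0, 1], rownames = left region_ids), `ds`
#'   (tibble), and `provenance` (per-step counts).
#' @export
build_region_gene_matrix <- function(bundle, atlas, config = list()) {
  cfg <- utils::modifyList(list(
    min_fraction = 0.5, intensity_pooling = "pooled",
    max_distance = 2, left_only = TRUE,
    ds_mode = "top_fraction", ds_threshold = 0.5,
    reannotate = TRUE
  ), config)
  prov <- list(n_probes_initial = nrow(bundle$probes))

  # (i) re-annotation
  probes <- bundle$probes
  if (isTRUE(cfg$reannotate) && !is.null(bundle$probe_mapping)) {
    probes <- reannotate_probes(probes, bundle$probe_mapping)
    prov$reannotation_dropped <- attr(probes, "dropped")
  } else {
    prov$reannotation_dropped <- c(missing = 0L, ambiguous = 0L, contradicted = 0L)
  }
  prov$n_probes_annotated <- nrow(probes)

  # (ii) intensity filter
  surviving <- filter_probes_intensity(bundle, cfg$min_fraction,
                                       cfg$intensity_pooling)
  surviving <- intersect(surviving, probes$probe_id)
  prov$n_probes_intensity <- length(surviving)
  prov$n_probes_dropped_intensity <- prov$n_probes_annotated - length(surviving)
  if (!length(surviving)) stop_msntx("intensity filter removed every probe.", "pipeline_halt")

  # (iii) probe selection
  sub_bundle <- bundle
  sub_bundle$probes <- probes
  selection <- select_probes(sub_bundle, surviving)
  prov$n_genes_selected <- nrow(selection)

  # (iv) sample assignment
  assign <- assign_samples(bundle, atlas, cfg$max_distance, cfg$left_only)
  prov$n_samples_total <- nrow(assign)
  prov$n_samples_assigned <- sum(!is.na(assign$region_id))
  prov$n_samples_unassigned <- sum(is.na(assign$region_id))
  if (!prov$n_samples_assigned) stop_msntx("sample assignment emptied the data.", "pipeline_halt")

  # per donor: region x gene means on selected probes, then (v) SRS
  pid <- as.character(selection$probe_id)
  donor_mats <- purrr::imap(bundle$donors, function(don, dn) {
    keep <- assign$donor_id == dn & !is.na(assign$region_id)
    sid <- assign$sample_id[keep]
    if (!length(sid)) return(NULL)
    expr <- don$expression[pid, sid, drop = FALSE]
    f <- factor(assign$region_id[keep])
    m <- t(rowsum(t(expr), f) / as.numeric(table(f)))   # probes x regions
    m <- t(m)                                           # regions x genes
    colnames(m) <- selection$gene_symbol
    srs_normalize(m)
  })
  donor_mats <- donor_mats[!vapply(donor_mats, is.null, logical(1))]
  if (length(donor_mats) < 2) stop_msntx("fewer than 2 donors with assigned samples.", "pipeline_halt")

  # (vi) differential stability
  if (identical(cfg$ds_mode, "none")) {
    ds <- list(genes = selection$gene_symbol,
               ds = tibble::tibble(gene = selection$gene_symbol, ds = NA_real_))
  } else {
    ds <- differential_stability_filter(donor_mats, cfg$ds_mode, cfg$ds_threshold)
  }
  prov$n_genes_after_ds <- length(ds$genes)
  if (!length(ds$genes)) stop_msntx("differential stability filter removed every gene.", "pipeline_halt")

  # donor aggregation: mean across donors per region over retained genes
  all_regions <- sort(unique(unlist(purrr::map(donor_mats, rownames))))
  sums <- matrix(0, length(all_regions), length(ds$genes),
                 dimnames = list(all_regions, ds$genes))
  cnt <- matrix(0, length(all_regions), length(ds$genes))
  for (m in donor_mats) {
    idx <- match(rownames(m), all_regions)
    sums[idx, ] <- sums[idx, ] + m[, ds$genes, drop = FALSE]
    cnt[idx, ] <- cnt[idx, ] + 1
  }
  values <- sums / cnt
  prov$n_regions <- nrow(values)

  structure(list(values = values, ds = ds$ds, provenance = prov,
                 selection = selection),
            class = "region_gene_matrix")
}

#' @export
print.region_gene_matrix <- function(x, ...) {
  cat(sprintf("<region_gene_matrix> %d regions x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as_tibble.region_gene_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(region_id = as.integer(rownames(x$values))),
    tibble::as_tibble(x$values)
  )
}

#' Write a region x gene matrix and its provenance to disk
#'
#' @param x a `region_gene_matrix`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_region_gene_matrix <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble::as_tibble(x), file.path(dir, "region_gene_matrix.tsv"))
  readr::write_tsv(x$ds, file.path(dir, "ds.tsv"))
  writeLines(jsonlite::toJSON(x$provenance, auto_unbox = TRUE, digits = NA),
             file.path(dir, "provenance.json"))
  invisible(dir)
}
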