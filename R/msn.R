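#' Z-normalize morphometric features across regions
#'
#' Each feature column is standardized across regions (mean 0, sample SD 1,
#' denominator n - 1) so that features measured in incommensurate units
#' contribute equally to the between-region correlations. If a `subject_id`
#' column is present, standardization is done within subject.
#'
#' @param features data frame with `region_id`, optional `subject_id`, and
#'   numeric feature columns.
#' @return tibble of the same shape with standardized feature columns.
#' @export
zscore_features <- function(features) {
  features <- tibble::as_tibble(features)
  fcols <- feature_cols(features)
  zs <- function(df) {
    for (fc in fcols) {
      v <- df[[fc]]
      s <- sd(v)
      if (!is.finite(s) || s == 0) {
        stop_msntx(sprintf("feature `%s` is constant across regions.", fc),
                   "degenerate_input")
      }
      df[[fc]] <- (v - mean(v)) / s
    }
    df
  }
  if ("subject_id" %in% names(features)) {
    features |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::group_modify(~ zs(.x)) |>
      dplyr::ungroup() |>
      dplyr::relocate("subject_id")
  } else {
    zs(features)
  }
}

feature_cols <- function(features) {
  setdiff(names(features)[vapply(features, is.numeric, logical(1))],
          c("region_id"))
}

#' Build a morphometric similarity network for one subject
#'
#' Computes the region x region matrix of Pearson correlations between
#' regions' z-scored feature vectors (correlation over the F features), with
#' the diagonal set to zero. Refuses visibly non-standardized input unless
#' `allow_raw = TRUE`, because the correlation is only meaningful after
#' features have been z-normalized across regions.
#'
#' @param features single-subject data frame (`region_id` + feature columns),
#'   already passed through [zscore_features()].
#' @param allow_raw skip the standardization check.
#' @return object of class `msn_matrix`: list with `weights` (symmetric
#'   matrix, zero diagonal, region_ids as dimnames), `density` (1 for the
#'   unthresholded network) and `region_id`.
#' @export
build_msn <- function(features, allow_raw = FALSE) {
  features <- tibble::as_tibble(features)
  if ("subject_id" %in% names(features) &&
      dplyr::n_distinct(features$subject_id) > 1) {
    stop_msntx("`build_msn()` takes one subject at a time; see `compute_strengths()`.",
               "invalid_argument")
  }
  fcols <- feature_cols(features)
  if (length(fcols) < 3) stop_msntx("need >= 3 features.", "invalid_argument")
  m <- as.matrix(features[, fcols])
  if (nrow(m) < 2) stop_msntx("need >= 2 regions.", "invalid_argument")
  if (anyNA(m)) stop_msntx("features contain missing values.", "invalid_argument")
  if (!allow_raw) {
    mu <- colMeans(m); s <- apply(m, 2, sd)
    if (max(abs(mu)) > 1e-6 || max(abs(s - 1)) > 1e-6) {
      stop_msntx("features do not look z-scored; run zscore_features() first or set allow_raw = TRUE.",
                 "invalid_argument")
    }
  }
  rsd <- apply(m, 1, sd)
  if (any(rsd == 0)) {
    stop_msntx(sprintf("region(s) %s have constant feature vectors.",
                       paste(features$region_id[rsd == 0], collapse = ", ")),
               "degenerate_input")
  }
  w <- cor(t(m))
  diag(w) <- 0
  dimnames(w) <- list(features$region_id, features$region_id)
  structure(list(weights = w, density = 1, region_id = features$region_id),
            class = "msn_matrix")
}

#' Threshold an MSN at a target connection density
#'
#' Retains the top `density` fraction of off-diagonal entries ranked by
#' signed correlation (the strongest positive correlations are kept; with
#' `mode = "absolute"`, by magnitude), zeroing the rest symmetrically. Ties
#' are broken by (row, column) lexicographic order of the upper-triangle
#' pair. Kept-edge sets are nested across densities. `density = 1` returns
#' the input unchanged.
#'
#' @param msn an `msn_matrix`.
#' @param density target density in (0, 1].
#' @param mode rank edges by signed value (default) or absolute value.
#' @return thresholded `msn_matrix` with its `density` field updated.
#' @export
threshold_msn <- function(msn, density, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (!is.numeric(density) || length(density) != 1 || is.na(density) ||
      density <= 0 || density > 1) {
    stop_msntx("`density` must lie in (0, 1].", "invalid_argument")
  }
  if (density == 1) return(msn)
  w <- msn$weights
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  vals <- w[ut]
  key <- if (mode == "signed") -vals else -abs(vals)
  ord <- order(key, ut[, 1], ut[, 2])
  n_pairs <- ceiling(density * n * (n - 1) / 2)
  keep <- ord[seq_len(n_pairs)]
  out <- matrix(0, n, n, dimnames = dimnames(w))
  ij <- ut[keep, , drop = FALSE]
  out[ij] <- vals[keep]
  out[ij[, c(2, 1), drop = FALSE]] <- vals[keep]
  structure(list(weights = out, density = density, region_id = msn$region_id),
            class = "msn_matrix")
}

#' Regional MSN strength
#'
#' The per-region statistic of the analysis: the signed sum of a region's
#' correlation weights to all other regions. Negative weights are included
#' and no normalization is applied.
#'
#' @param msn an `msn_matrix`.
#' @return tibble (region_id, strength).
#' @export
regional_strength <- function(msn) {
  tibble::tibble(region_id = msn$region_id,
                 strength = as.numeric(rowSums(msn$weights)))
}

#' Per-subject regional strengths for a whole cohort
#'
#' Convenience wrapper running z-scoring, MSN construction, optional density
#' thresholding and strength reduction for every subject in a long feature
#' table.
#'
#' @param features tibble with `subject_id`, `region_id` and feature columns.
#' @param density connection density passed to [threshold_msn()].
#' @param mode edge-ranking mode for thresholding.
#' @return tibble (subject_id, region_id, strength).
#' @export
compute_strengths <- function(features, density = 1, mode = "signed") {
  features |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      z <- zscore_features(df)
      msn <- build_msn(z)
      if (density < 1) msn <- threshold_msn(msn, density, mode)
      regional_strength(msn)
    }) |>
    dplyr::ungroup()
}

#' @export
print.msn_matrix <- function(x, ...) {
  cat(sprintf("<msn_matrix> %d regions, density %.2f\n",
              nrow(x$weights), x$density))
  invisible(x)
}

#' Tidy an MSN into an edge table
#'
#' @param x an `msn_matrix`.
#' @param ... unused.
#' @return tibble (region_a, region_b, weight) over upper-triangle pairs.
#' @export
tidy.msn_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$weights), arr.ind = TRUE)
  tibble::tibble(
    region_a = x$region_id[ut[, 1]],
    region_b = x$region_id[ut[, 2]],
    weight = x$weights[ut]
  )
}
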