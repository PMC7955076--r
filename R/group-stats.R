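#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, clipped to [0, 1] and monotone in p-rank.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same length.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0) || any(p_values > 1)) {
    stop_msntx("p-values must be in [0, 1].", "invalid_argument")
  }
  p.adjust(p_values, method = "BH")
}

# Internal: strengths long table -> subjects x regions matrix aligned to a
# participant table.
strengths_matrix <- function(strengths, participants, value_col = "strength",
                             unit_col = "region_id") {
  wide <- strengths |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = dplyr::all_of(unit_col),
                       values_from = dplyr::all_of(value_col))
  wide <- wide[match(participants$subject_id, wide$subject_id), ]
  if (anyNA(wide$subject_id)) {
    stop_msntx("strengths missing for some participants.", "invalid_argument")
  }
  y <- as.matrix(wide[, -1, drop = FALSE])
  rownames(y) <- wide$subject_id
  y
}

#' Case-control regional t-map from a linear regression model
#'
#' Per region, fits ordinary least squares of regional MSN strength on an
#' intercept, a case/control indicator and the requested covariates, and
#' extracts the two-sided t-statistic of the group coefficient
#' (contrast = case - control) with n - k residual degrees of freedom.
#' P-values are BH-FDR adjusted across regions.
#'
#' @param strengths tibble (subject_id, region_id, strength).
#' @param participants tibble with `subject_id`, a group column and covariates.
#' @param covariates covariate column names (default age, sex, education; add
#'   "tiv" to reproduce the intracranial-volume sensitivity model).
#' @param group_col,case,control group column and its case/control levels.
#' @return tibble of class `msn_tmap` (region_id, t, p, q) with attributes
#'   `df`, `n`, `contrast` and `fdr_family`.
#' @export
fit_tmap <- function(strengths, participants,
                     covariates = c("age", "sex", "education"),
                     group_col = "group", case = "case", control = "control") {
  participants <- tibble::as_tibble(participants)
  grp <- participants[[group_col]]
  if (is.null(grp) || !all(c(case, control) %in% grp)) {
    stop_msntx("both groups must be present.", "invalid_argument")
  }
  covs <- participants[, covariates, drop = FALSE]
  if (anyNA(covs)) stop_msntx("missing covariate values.", "invalid_argument")
  y <- strengths_matrix(strengths, participants)
  n <- nrow(y)
  x <- cbind(`(Intercept)` = 1, group = as.numeric(grp == case),
             as.matrix(covs))
  k <- ncol(x)
  if (n <= k + 1) stop_msntx("too few subjects for the design.", "invalid_argument")
  qx <- qr(x)
  if (qx$rank < k) stop_msntx("rank-deficient design.", "singular_design")
  cf <- qr.coef(qx, y)
  res <- y - x %*% cf
  df <- n - k
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtxinv[2, 2])
  tval <- cf["group", ] / se
  p <- 2 * pt(-abs(tval), df)
  out <- tibble::tibble(
    region_id = utils::type.convert(colnames(y), as.is = TRUE),
    t = as.numeric(tval), p = as.numeric(p), q = bh_fdr(p)
  )
  attr(out, "df") <- df
  attr(out, "n") <- n
  attr(out, "contrast") <- paste(case, "-", control)
  attr(out, "fdr_family") <- sprintf("%d regions", ncol(y))
  class(out) <- c("msn_tmap", class(out))
  out
}

#' Quadrant classification of regional effects
#'
#' Crosses the sign of the case-control t with the sign of the control-group
#' mean strength: negative t with positive mean strength is "decoupling"
#' (connected regions becoming less similar to the rest of cortex in cases);
#' positive t with negative mean is "dedifferentiation"; the remaining strict
#' quadrants are "coupled_increase" and "differentiated_decrease". Exact
#' zeros map to "null".
#'
#' @param tmap an `msn_tmap` (or tibble with region_id, t).
#' @param control_mean_strength tibble (region_id, strength) of control means.
#' @return tibble (region_id, t, mean_strength, label) with a `fractions`
#'   attribute giving each label's share of all regions.
#' @export
classify_regions <- function(tmap, control_mean_strength) {
  df <- dplyr::inner_join(
    tibble::as_tibble(tmap)[, c("region_id", "t")],
    dplyr::rename(control_mean_strength, mean_strength = "strength"),
    by = "region_id"
  )
  if (nrow(df) != nrow(tmap)) {
    stop_msntx("region sets do not match.", "invalid_argument")
  }
  df$label <- dplyr::case_when(
    df$t == 0 | df$mean_strength == 0 ~ "null",
    df$t < 0 & df$mean_strength > 0 ~ "decoupling",
    df$t > 0 & df$mean_strength < 0 ~ "dedifferentiation",
    df$t > 0 & df$mean_strength > 0 ~ "coupled_increase",
    TRUE ~ "differentiated_decrease"
  )
  lv <- c("decoupling", "dedifferentiation", "coupled_increase",
          "differentiated_decrease", "null")
  frac <- table(factor(df$label, levels = lv)) / nrow(df)
  attr(df, "fractions") <- setNames(as.numeric(frac), lv)
  df
}

#' System-level case-control statistics
#'
#' Averages each subject's regional strengths within each labelled system
#' (e.g. functional networks or cytoarchitectonic classes), then fits the
#' same covariate-adjusted group model per system, with BH-FDR across
#' systems.
#'
#' @param strengths tibble (subject_id, region_id, strength).
#' @param atlas a `parcel_atlas` carrying the label column.
#' @param scheme label column name in the atlas (e.g. "yeo7", "veconomo").
#' @param participants participant table (see [fit_tmap()]).
#' @param covariates covariates for the linear model.
#' @return tibble (system, t, p, q).
#' @export
aggregate_by_system <- function(strengths, atlas, scheme, participants,
                                covariates = c("age", "sex", "education")) {
  if (!scheme %in% names(atlas)) {
    stop_msntx(sprintf("scheme `%s` not in atlas.", scheme), "invalid_argument")
  }
  sys_strength <- strengths |>
    dplyr::inner_join(atlas[, c("region_id", scheme)], by = "region_id") |>
    dplyr::group_by(.data$subject_id, system = .data[[scheme]]) |>
    dplyr::summarise(strength = mean(.data$strength), .groups = "drop") |>
    dplyr::rename(region_id = "system")
  out <- fit_tmap(sys_strength, participants, covariates)
  out <- dplyr::rename(tibble::as_tibble(out), system = "region_id")
  attr(out, "fdr_family") <- sprintf("%d systems", nrow(out))
  out
}

#' Correlate regional strengths with symptom scores
#'
#' Per-region Pearson correlation between subjects' strengths and a clinical
#' score (e.g. depression or anxiety rating scales), with two-sided p from
#' the t transform on n - 2 degrees of freedom and BH-FDR across the region
#' family (all regions, or a named subset when given).
#'
#' @param strengths tibble (subject_id, region_id, strength).
#' @param participants participant table carrying the score.
#' @param score_col score column name.
#' @param case_only restrict to case subjects (default; set FALSE to pool).
#' @param regions optional region_id subset defining the FDR family.
#' @param group_col,case group column/level for the case-only subset.
#' @return tibble (region_id, r, p, q).
#' @export
correlate_symptoms <- function(strengths, participants, score_col,
                               case_only = TRUE, regions = NULL,
                               group_col = "group", case = "case") {
  participants <- tibble::as_tibble(participants)
  if (case_only) participants <- participants[participants[[group_col]] == case, ]
  if (nrow(participants) < 4) stop_msntx(">= 4 subjects required.", "invalid_argument")
  scores <- participants[[score_col]]
  if (sd(scores) == 0) stop_msntx("scores are constant.", "degenerate_input")
  y <- strengths_matrix(strengths[strengths$subject_id %in% participants$subject_id, ],
                        participants)
  if (!is.null(regions)) y <- y[, colnames(y) %in% as.character(regions), drop = FALSE]
  n <- nrow(y)
  r <- as.numeric(cor(y, scores))
  tval <- r * sqrt(n - 2) / sqrt(pmax(1e-300, 1 - r^2))
  p <- 2 * pt(-abs(tval), n - 2)
  tibble::tibble(
    region_id = utils::type.convert(colnames(y), as.is = TRUE),
    r = r, p = p, q = bh_fdr(p)
  )
}

#' Spatial concordance of two regional maps
#'
#' Pearson correlation of two maps over the same parcellation with a spin
#' permutation p-value (map_a is spun).
#'
#' @param map_a,map_b numeric region vectors (aligned with `spins`) or
#'   tibbles with `region_id` and a value column.
#' @param spins a `spin_set` from [generate_spins()].
#' @param alternative "two_sided" (default), "greater" or "less".
#' @return one-row tibble (r, p_spin, n_regions).
#' @export
map_concordance <- function(map_a, map_b, spins, alternative = "two_sided") {
  a <- as_region_vector(map_a, spins$region_id)
  b <- as_region_vector(map_b, spins$region_id)
  res <- spin_correlation_test(a, b, spins, method = "pearson",
                               alternative = alternative)
  tibble::tibble(r = res$r_observed, p_spin = res$p_spin,
                 n_regions = length(a))
}

# Internal: coerce a map to a numeric vector aligned with region_ids.
as_region_vector <- function(x, region_id) {
  if (is.data.frame(x)) {
    vcol <- setdiff(names(x), "region_id")[1]
    idx <- match(region_id, x$region_id)
    if (anyNA(idx)) stop_msntx("map does not cover all spin regions.", "invalid_argument")
    return(as.numeric(x[[vcol]][idx]))
  }
  if (!is.null(names(x))) {
    idx <- match(as.character(region_id), names(x))
    if (!anyNA(idx)) return(as.numeric(x[idx]))
  }
  if (length(x) != length(region_id)) {
    stop_msntx("map length does not match the spin region set.", "invalid_argument")
  }
  as.numeric(x)
}
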