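#' First-component partial least squares of a regional map on gene expression
#'
#' With a univariate response, the first PLS component has a closed form:
#' after centering (and, by default, z-scoring) the predictor columns and
#' centering the response, the unit-norm weight vector is proportional to
#' `t(X) %*% y` — the direction in gene space with maximal covariance with
#' the map. Regional scores are the projection of the centered predictors on
#' that direction, and the variance explained is the squared Pearson
#' correlation between scores and response. The component sign is fixed so
#' that scores correlate positively with the response, making the negative
#' gene list reproducibly mean "expression high where the map is low".
#'
#' @param x a `region_gene_matrix`, or a numeric region x gene matrix with
#'   region_ids as rownames, or a tibble with `region_id` + gene columns.
#' @param y regional response: named numeric vector, or tibble
#'   (region_id, value). Only regions present in both are used.
#' @param scale_x z-score predictor columns (default TRUE; expression values
#'   live on [0, 1] with unequal variances, so standardization keeps highly
#'   variable genes from dominating).
#' @return object of class `msn_pls`: list with `weights` (named, unit norm),
#'   `scores` (named by region), `var_explained`, `y`, `regions`, and the
#'   centering/scaling needed to refit.
#' @export
fit_pls1 <- function(x, y, scale_x = TRUE) {
  xm <- as_gene_matrix(x)
  yv <- align_response(y, rownames(xm))
  xm <- xm[names(yv), , drop = FALSE]
  if (nrow(xm) < 3) stop_msntx(">= 3 regions required.", "invalid_argument")
  if (ncol(xm) < 2) stop_msntx(">= 2 genes required.", "invalid_argument")
  if (sd(yv) == 0) stop_msntx("response has zero variance.", "degenerate_input")
  fit <- pls1_core(xm, yv, scale_x)
  structure(c(fit, list(y = yv, regions = rownames(xm), scale_x = scale_x)),
            class = "msn_pls")
}

# Internal closed-form PLS1 on a prepared matrix.
pls1_core <- function(xm, yv, scale_x) {
  xc <- scale(xm, center = TRUE, scale = FALSE)
  if (scale_x) {
    s <- apply(xm, 2, sd)
    s[s == 0] <- 1
    xc <- sweep(xc, 2, s, "/")
  }
  yc <- yv - mean(yv)
  w <- as.numeric(crossprod(xc, yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop_msntx("predictors are uncorrelated with the response everywhere.",
                          "degenerate_input")
  w <- w / nw
  scores <- as.numeric(xc %*% w)
  r <- cor(scores, yv)
  if (r < 0) { w <- -w; scores <- -scores; r <- -r }
  list(weights = setNames(w, colnames(xm)),
       scores = setNames(scores, rownames(xm)),
       var_explained = r^2)
}

as_gene_matrix <- function(x) {
  if (inherits(x, "region_gene_matrix")) return(x$values)
  if (is.data.frame(x)) {
    m <- as.matrix(x[, setdiff(names(x), "region_id"), drop = FALSE])
    rownames(m) <- x$region_id
    return(m)
  }
  as.matrix(x)
}

align_response <- function(y, regions) {
  if (is.data.frame(y)) {
    vcol <- setdiff(names(y), "region_id")[1]
    y <- setNames(y[[vcol]], y$region_id)
  }
  if (is.null(names(y))) {
    if (length(y) != length(regions)) {
      stop_msntx("unnamed response must match the matrix regions.", "invalid_argument")
    }
    names(y) <- regions
  }
  common <- intersect(regions, names(y))
  if (length(common) < 3) stop_msntx("fewer than 3 shared regions.", "invalid_argument")
  y[common]
}

#' Spin test for the variance explained by the first PLS component
#'
#' Refits the first component against spatially rotated versions of the
#' response map (the map is spun; the gene matrix stays fixed) and compares
#' the observed variance explained to that null with `alternative =
#' "greater"`. This tests whether genes track the map more closely than
#' expected for maps with the same spatial autocorrelation.
#'
#' @param x predictors (see [fit_pls1()]).
#' @param y regional response map.
#' @param spins a `spin_set` over the matrix's region set.
#' @param scale_x as in [fit_pls1()].
#' @return list (var_explained, p_spin, null).
#' @export
pls_spin_test <- function(x, y, spins, scale_x = TRUE) {
  xm <- as_gene_matrix(x)
  yv <- align_response(y, rownames(xm))
  xm <- xm[names(yv), , drop = FALSE]
  if (!setequal(names(yv), as.character(spins$region_id))) {
    stop_msntx("spin set does not cover the matrix regions.", "invalid_argument")
  }
  ord <- match(as.character(spins$region_id), names(yv))
  yv <- yv[ord]; xm <- xm[ord, , drop = FALSE]
  n <- length(yv)

  xc <- scale(xm, center = TRUE, scale = FALSE)
  if (scale_x) {
    s <- apply(xm, 2, sd); s[s == 0] <- 1
    xc <- sweep(xc, 2, s, "/")
  }
  obs <- pls1_core(xm, yv, scale_x)$var_explained

  perm <- spins$permutations
  ym <- matrix(yv[t(perm)], nrow = n)                 # regions x spins
  ymc <- sweep(ym, 2, colMeans(ym))
  w <- crossprod(xc, ymc)                             # genes x spins
  sc <- xc %*% w                                      # regions x spins
  # columnwise cor(scores, spun y)^2
  num <- colSums(sweep(sc, 2, colMeans(sc)) * ymc)
  den <- sqrt(colSums(sweep(sc, 2, colMeans(sc))^2) * colSums(ymc^2))
  nulls <- (num / den)^2
  nulls[!is.finite(nulls)] <- 0
  list(var_explained = obs,
       p_spin = spin_pvalue(obs, nulls, "greater"),
       null = as.numeric(nulls))
}

#' Bootstrap Z-scores for PLS1 gene weights
#'
#' Resamples regions (the observational units of the regression) with
#' replacement, refits the first component, sign-aligns each replicate to
#' the original weights (all signs flip when the dot product with the
#' original is negative), and summarizes each gene as
#' `z = weight / bootstrap SE`. Two-sided normal p-values are BH-FDR
#' adjusted across genes.
#'
#' @param x predictors (see [fit_pls1()]).
#' @param y regional response map.
#' @param n_boot bootstrap replicates (>= 2; 1000 is typical).
#' @param seed integer seed.
#' @param scale_x as in [fit_pls1()].
#' @return tibble of class `pls_gene_z` (gene, weight, bootstrap_se, z, q),
#'   sorted by descending z.
#' @export
bootstrap_gene_weights <- function(x, y, n_boot = 1000, seed = 1, scale_x = TRUE) {
  if (n_boot < 2) stop_msntx("`n_boot` must be >= 2.", "invalid_argument")
  n_boot <- check_positive_int(n_boot, "n_boot")
  xm <- as_gene_matrix(x)
  yv <- align_response(y, rownames(xm))
  xm <- xm[names(yv), , drop = FALSE]
  n <- nrow(xm)
  if (n < 10) warn("bootstrap over fewer than 10 regions is unstable.")
  orig <- pls1_core(xm, yv, scale_x)
  w0 <- orig$weights

  wb <- withr::with_seed(seed, {
    out <- matrix(NA_real_, length(w0), n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- yv[idx]
      if (sd(yb) == 0) next
      fb <- tryCatch(pls1_core(xm[idx, , drop = FALSE], yb, scale_x),
                     error = function(e) NULL)
      if (is.null(fb)) next
      wv <- fb$weights
      if (sum(wv * w0) < 0) wv <- -wv
      out[, b] <- wv
    }
    out
  })
  se <- apply(wb, 1, sd, na.rm = TRUE)
  z <- as.numeric(w0) / se
  p <- 2 * pnorm(-abs(z))
  out <- tibble::tibble(gene = names(w0), weight = as.numeric(w0),
                        bootstrap_se = se, z = z, q = bh_fdr(p))
  out <- dplyr::arrange(out, dplyr::desc(.data$z))
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  class(out) <- c("pls_gene_z", class(out))
  out
}

#' Extract thresholded positive/negative gene lists
#'
#' The positive list holds genes with `z > z_threshold` and
#' `q < fdr_threshold`; the negative list is symmetric. Both are ordered by
#' decreasing |z|.
#'
#' @param ztable a `pls_gene_z` table.
#' @param z_threshold |Z| cut-off (default 5).
#' @param fdr_threshold FDR cut-off (default 0.005, i.e. 5 per mille).
#' @return list of class `gene_lists` with `pls1_plus`, `pls1_minus`, and
#'   `thresholds`.
#' @export
extract_gene_lists <- function(ztable, z_threshold = 5, fdr_threshold = 0.005) {
  plus <- ztable[ztable$z > z_threshold & ztable$q < fdr_threshold, ]
  minus <- ztable[ztable$z < -z_threshold & ztable$q < fdr_threshold, ]
  structure(
    list(
      pls1_plus = plus$gene[order(-abs(plus$z))],
      pls1_minus = minus$gene[order(-abs(minus$z))],
      thresholds = list(z = z_threshold, fdr = fdr_threshold)
    ),
    class = "gene_lists"
  )
}

#' @export
print.gene_lists <- function(x, ...) {
  cat(sprintf("<gene_lists> %d positive, %d negative (|Z| > %g, FDR < %g)\n",
              length(x$pls1_plus), length(x$pls1_minus),
              x$thresholds$z, x$thresholds$fdr))
  invisible(x)
}

#' Correlate individual gene maps with a regional response
#'
#' Pearson correlation between each listed gene's regional expression profile
#' and the response map, with a spin p-value (the response map is spun) and
#' BH-FDR across the supplied gene set (the gene family being tested, e.g. a
#' prior disease-gene panel).
#'
#' @param genes character gene symbols (the FDR family).
#' @param x a `region_gene_matrix` (or matrix/tibble).
#' @param y regional response map.
#' @param spins a `spin_set` over the matrix regions.
#' @param alternative passed to [spin_pvalue()] (default "two_sided").
#' @return tibble (gene, r, p_spin, q).
#' @export
gene_map_correlation <- function(genes, x, y, spins, alternative = "two_sided") {
  xm <- as_gene_matrix(x)
  missing <- setdiff(genes, colnames(xm))
  if (length(missing)) {
    stop_msntx(sprintf("gene(s) not in the matrix: %s",
                       paste(missing, collapse = ", ")), "invalid_argument")
  }
  yv <- align_response(y, rownames(xm))
  res <- purrr::map(genes, function(g) {
    prof <- setNames(xm[names(yv), g], names(yv))
    st <- spin_correlation_test(yv, prof, spins, "pearson", alternative)
    tibble::tibble(gene = g, r = st$r_observed, p_spin = st$p_spin)
  })
  out <- dplyr::bind_rows(res)
  out$q <- bh_fdr(out$p_spin)
  out
}

#' @export
print.msn_pls <- function(x, ...) {
  cat(sprintf("<msn_pls> %d genes over %d regions; component 1 explains %.1f%% of map variance\n",
              length(x$weights), length(x$regions), 100 * x$var_explained))
  invisible(x)
}

#' Tidy method for PLS fits: one row per gene weight
#'
#' @param x an `msn_pls`.
#' @param ... unused.
#' @return tibble (gene, weight).
#' @export
tidy.msn_pls <- function(x, ...) {
  tibble::tibble(gene = names(x$weights), weight = as.numeric(x$weights))
}

#' Glance method for PLS fits: one-row model summary
#'
#' @param x an `msn_pls`.
#' @param ... unused.
#' @return one-row tibble (var_explained, n_regions, n_genes).
#' @export
glance.msn_pls <- function(x, ...) {
  tibble::tibble(var_explained = x$var_explained,
                 n_regions = length(x$regions),
                 n_genes = length(x$weights))
}

#' Write gene-level association outputs
#'
#' Writes `gene_z.tsv`, `pls1_plus.txt` / `pls1_minus.txt` (one symbol per
#' line) and `pls_result.json`.
#'
#' @param ztable a `pls_gene_z` table.
#' @param lists a `gene_lists` object.
#' @param pls_summary named list stored as JSON (e.g. var_explained, p_spin,
#'   seed, settings).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_association <- function(ztable, lists, pls_summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(ztable, file.path(dir, "gene_z.tsv"))
  writeLines(lists$pls1_plus, file.path(dir, "pls1_plus.txt"))
  writeLines(lists$pls1_minus, file.path(dir, "pls1_minus.txt"))
  writeLines(jsonlite::toJSON(pls_summary, auto_unbox = TRUE, digits = NA),
             file.path(dir, "pls_result.json"))
  invisible(dir)
}
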