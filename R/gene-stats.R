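#' Spearman correlation between PLS gene weights and differential expression
#'
#' Correlates the PLS weights of a gene list with published
#' differential-expression effects restricted to one direction ("up" or
#' "down"), over the genes common to both. The null relabels the up/down
#' direction assignments across all differentially expressed genes (per-
#' direction counts preserved) and recomputes the correlation each time;
#' the permutation p uses the add-one correction. When the DGE table spans
#' several disorders, run once per disorder and BH-adjust with
#' [dge_spearman_panel()].
#'
#' @param weights tibble with `gene` and a weight column (`weight` or `z`),
#'   typically a `pls_gene_z` restricted to one extracted list.
#' @param dge tibble (gene, dge_value, direction) for one disorder.
#' @param direction which DGE direction to correlate against ("up"/"down").
#' @param n_perm number of relabelings (default 5000).
#' @param seed integer seed.
#' @param alternative "two_sided" (default), "less" or "greater".
#' @return one-row tibble (direction, n_common, rho, p_perm).
#' @export
dge_spearman_test <- function(weights, dge, direction = "up", n_perm = 5000,
                              seed = 1, alternative = "two_sided") {
  n_perm <- check_positive_int(n_perm, "n_perm")
  wcol <- intersect(c("weight", "z"), names(weights))[1]
  if (is.na(wcol)) stop_msntx("`weights` needs a weight or z column.", "invalid_argument")
  w <- setNames(weights[[wcol]], weights$gene)

  dsub <- dge[dge$direction == direction, ]
  common <- intersect(names(w), dsub$gene)
  if (length(common) < 3) {
    stop_msntx("fewer than 3 genes shared with the DGE set.", "insufficient_overlap")
  }
  obs <- cor(w[common], dsub$dge_value[match(common, dsub$gene)],
             method = "spearman")

  in_list <- dge$gene %in% names(w)
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- sample(dge$direction)          # relabel, counts preserved
      sub <- which(lab == direction & in_list)
      if (length(sub) < 3) return(NA_real_)
      cor(w[dge$gene[sub]], dge$dge_value[sub], method = "spearman")
    }, numeric(1))
  })
  nulls <- nulls[!is.na(nulls)]
  tibble::tibble(direction = direction, n_common = length(common), rho = obs,
                 p_perm = spin_pvalue(obs, nulls, alternative))
}

#' DGE correlations across a panel of disorders, FDR-adjusted
#'
#' @param weights as in [dge_spearman_test()].
#' @param dge tibble with a `disorder` column.
#' @param direction DGE direction.
#' @param n_perm,seed,alternative as in [dge_spearman_test()].
#' @return tibble (disorder, direction, n_common, rho, p_perm, q).
#' @export
dge_spearman_panel <- function(weights, dge, direction = "up", n_perm = 5000,
                               seed = 1, alternative = "two_sided") {
  out <- dge |>
    dplyr::group_by(.data$disorder) |>
    dplyr::group_modify(function(df, key) {
      dge_spearman_test(weights, df, direction, n_perm,
                        derive_seed(seed, nchar(key$disorder)), alternative)
    }) |>
    dplyr::ungroup()
  out$q <- bh_fdr(out$p_perm)
  out
}

#' Permutation overlap test between a gene list and cell-type sets
#'
#' For each cell class, counts genes shared between `gene_list` and the
#' class set, and compares that count to overlaps with size-matched random
#' gene sets drawn from the background universe (the cell set is resampled,
#' not the list; set `resample = "list"` for the sensitivity variant).
#' P-values use the add-one correction and are BH-adjusted across classes.
#'
#' @param gene_list character gene symbols.
#' @param sets named list of cell-class gene sets.
#' @param background the gene universe (typically the post-filtering gene
#'   universe of the expression stage). Genes outside it are clipped with a
#'   warning.
#' @param n_perm random draws per class (default 5000).
#' @param seed integer seed.
#' @param resample resample the cell set (default) or the gene list.
#' @return tibble (cell_class, set_size, overlap, p_perm, q).
#' @export
celltype_overlap_test <- function(gene_list, sets, background, n_perm = 5000,
                                  seed = 1, resample = c("set", "list")) {
  n_perm <- check_positive_int(n_perm, "n_perm")
  resample <- match.arg(resample)
  if (!length(background)) stop_msntx("empty background universe.", "invalid_argument")
  clip <- function(g, what) {
    out <- intersect(g, background)
    if (length(out) < length(g)) {
      warn(sprintf("%d %s gene(s) outside the background were dropped.",
                   length(g) - length(out), what))
    }
    out
  }
  gene_list <- clip(unique(gene_list), "list")
  sets <- purrr::imap(sets, function(s, nm) clip(unique(s), nm))
  in_list <- background %in% gene_list
  nbg <- length(background)

  rows <- withr::with_seed(seed, {
    purrr::imap(sets, function(s, nm) {
      k <- length(s)
      observed <- length(intersect(gene_list, s))
      nulls <- if (resample == "set") {
        vapply(seq_len(n_perm), function(i) sum(in_list[sample.int(nbg, k)]),
               numeric(1))
      } else {
        in_set <- background %in% s
        kl <- length(gene_list)
        vapply(seq_len(n_perm), function(i) sum(in_set[sample.int(nbg, kl)]),
               numeric(1))
      }
      tibble::tibble(cell_class = nm, set_size = k, overlap = observed,
                     p_perm = (1 + sum(nulls >= observed)) / (n_perm + 1))
    })
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p_perm)
  out
}

#' Mean regional expression maps per cell class
#'
#' For each cell class, averages the regional expression profiles of the
#' genes shared between `gene_list` and the class set. Classes with empty
#' overlap are omitted (with a message).
#'
#' @param x a `region_gene_matrix` (or matrix/tibble).
#' @param gene_list character gene symbols.
#' @param sets named list of cell-class gene sets.
#' @return long tibble (region_id, cell_class, expression).
#' @export
celltype_expression_maps <- function(x, gene_list, sets) {
  xm <- as_gene_matrix(x)
  rows <- purrr::imap(sets, function(s, nm) {
    genes <- intersect(intersect(gene_list, s), colnames(xm))
    if (!length(genes)) {
      message(sprintf("cell class `%s` has no overlapping genes; omitted.", nm))
      return(NULL)
    }
    tibble::tibble(
      region_id = utils::type.convert(rownames(xm), as.is = TRUE),
      cell_class = nm,
      expression = as.numeric(rowMeans(xm[, genes, drop = FALSE]))
    )
  })
  dplyr::bind_rows(rows)
}

#' Odds ratio and Fisher exact p for the overlap of two gene lists
#'
#' Builds the 2x2 table (in both, A only, B only, neither) over a background
#' universe. The reported odds ratio is the sample estimate `ad / bc`, with
#' a Haldane correction of 0.5 added to every cell when any cell is zero;
#' the p-value is the two-sided Fisher exact test on the uncorrected table.
#'
#' @param list_a,list_b character gene symbol vectors.
#' @param background the gene universe (both lists must be subsets).
#' @return one-row tibble (odds_ratio, p, n11, n10, n01, n00).
#' @export
list_overlap_or <- function(list_a, list_b, background) {
  if (!length(background)) stop_msntx("empty background universe.", "invalid_argument")
  list_a <- unique(list_a); list_b <- unique(list_b)
  if (!all(list_a %in% background) || !all(list_b %in% background)) {
    stop_msntx("lists must be subsets of the background.", "invalid_argument")
  }
  a <- length(intersect(list_a, list_b))
  b <- length(setdiff(list_a, list_b))
  c_ <- length(setdiff(list_b, list_a))
  d <- length(background) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)
  or <- if (min(tab) == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  p <- fisher.test(tab)$p.value
  tibble::tibble(odds_ratio = or, p = p, n11 = a, n10 = b, n01 = c_, n00 = d)
}
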