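#' Simulate a postmortem differential-expression table
#'
#' Produces a table of per-gene differential-expression effects split into
#' up/downregulated sets, emulating published case-control postmortem DGE
#' resources. Planted genes receive effects anti-rank-correlated with their
#' planted loadings at strength `corr_strength` (genes tracking decreased
#' similarity appear upregulated postmortem, mirroring the direction
#' convention of case-control transcriptomic resources); background genes
#' are pure noise. At `corr_strength = 1` the planted effects are an exact
#' monotone function of the loadings (Spearman rho = -1).
#'
#' @param truth a `simulation_truth` (supplies planted genes and loadings).
#' @param n_background number of background genes to add.
#' @param corr_strength rank-correlation strength in [0, 1] between planted
#'   loadings and DGE effects.
#' @param disorder label stored in the `disorder` column.
#' @param seed integer seed; defaults to the truth's seed.
#' @return tibble (gene, dge_value, direction, disorder) with
#'   `direction = "up"` where dge_value > 0, `"down"` otherwise.
#' @export
simulate_dge_table <- function(truth, n_background, corr_strength,
                               disorder = "disorder_1", seed = NULL) {
  n_background <- check_positive_int(n_background, "n_background")
  corr_strength <- check_prob(corr_strength, "corr_strength")
  if (is.null(seed)) seed <- truth$seed
  planted <- truth$planted_genes
  load <- truth$planted_loading
  zload <- if (length(planted) > 1 && sd(load) > 0) {
    (load - mean(load)) / sd(load)
  } else {
    rep(0, length(planted))
  }
  withr::with_seed(derive_seed(seed, 41L), {
    eps <- rnorm(length(planted))
    dge_planted <- -corr_strength * zload +
      if (corr_strength < 1) sqrt(1 - corr_strength^2) * eps else 0
    bg <- tibble::tibble(
      gene = sprintf("bg_%05d", seq_len(n_background)),
      dge_value = rnorm(n_background)
    )
    out <- dplyr::bind_rows(
      tibble::tibble(gene = planted, dge_value = as.numeric(dge_planted)),
      bg
    )
    out$direction <- ifelse(out$dge_value > 0, "up", "down")
    out$disorder <- disorder
    out
  })
}

#' Build synthetic cell-type gene sets
#'
#' Draws `n_classes` gene sets from a gene universe. A class with enrichment
#' `e` and size `k` takes `round(e * k)` genes from the planted set (clipped
#' to its size) and the remainder from the rest of the universe. Sets may
#' overlap across classes, as real cell-type marker compilations do.
#'
#' When `n_classes = 7` the canonical class names are used (astrocytes,
#' endothelial, excitatory neurons, inhibitory neurons, microglia, OPCs,
#' oligodendrocytes); otherwise classes are `class_1`, `class_2`, ...
#'
#' @param gene_universe character vector of gene symbols.
#' @param n_classes number of cell classes.
#' @param class_sizes integer set sizes (recycled to `n_classes`).
#' @param enrichment named or unnamed numeric vector of planted-gene fractions
#'   per class (recycled; default 0).
#' @param planted_genes genes eligible for enrichment draws.
#' @param seed integer seed.
#' @return named list of character gene sets, class `cell_type_sets`.
#' @export
make_cell_sets <- function(gene_universe, n_classes, class_sizes,
                           enrichment = 0, planted_genes = character(),
                           seed = 1) {
  n_classes <- check_positive_int(n_classes, "n_classes")
  class_sizes <- rep_len(as.integer(class_sizes), n_classes)
  if (any(class_sizes > length(gene_universe))) {
    stop_msntx("class sizes cannot exceed the gene universe.", "invalid_argument")
  }
  enrichment <- rep_len(enrichment, n_classes)
  planted <- intersect(planted_genes, gene_universe)
  cls <- if (n_classes == 7L) {
    c("astrocytes", "endothelial", "excitatory_neurons", "inhibitory_neurons",
      "microglia", "OPCs", "oligodendrocytes")
  } else {
    sprintf("class_%d", seq_len(n_classes))
  }
  sets <- withr::with_seed(derive_seed(seed, 51L), {
    purrr::map(seq_len(n_classes), function(i) {
      k <- class_sizes[i]
      k_pl <- min(round(enrichment[i] * k), length(planted), k)
      from_planted <- if (k_pl > 0) sample(planted, k_pl) else character()
      pool <- setdiff(gene_universe, from_planted)
      rest <- if (k - k_pl > 0) sample(pool, k - k_pl) else character()
      sort(c(from_planted, rest))
    })
  })
  structure(setNames(sets, cls), class = "cell_type_sets")
}

#' Write / read gene sets as plain-text files (one symbol per line)
#'
#' @param sets named list of character vectors.
#' @param dir directory; one `<class>.txt` file per set.
#' @return `dir` invisibly (writer); a named list (reader).
#' @export
write_gene_sets <- function(sets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sets)) writeLines(sets[[nm]], file.path(dir, paste0(nm, ".txt")))
  invisible(dir)
}

#' @rdname write_gene_sets
#' @export
read_gene_sets <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  setNames(purrr::map(files, readLines), sub("\\.txt$", "", basename(files)))
}
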