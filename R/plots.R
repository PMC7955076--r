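#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   labs theme_minimal scale_colour_manual
NULL

#' Plot a case-control t-map
#'
#' Regional t-statistics ordered by region, with FDR-significant regions
#' highlighted.
#'
#' @param object an `msn_tmap`.
#' @param fdr significance threshold on q (default 0.05).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.msn_tmap <- function(object, fdr = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$q < fdr
  ggplot(df, aes(x = .data$region_id, y = .data$t, colour = .data$significant)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_point(size = 1) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                        name = sprintf("q < %g", fdr)) +
    labs(x = "region", y = "t (case - control)") +
    theme_minimal()
}

#' Plot regional PLS scores against the response map
#'
#' @param object an `msn_pls`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.msn_pls <- function(object, ...) {
  df <- tibble::tibble(score = object$scores, response = object$y)
  ggplot(df, aes(x = .data$score, y = .data$response)) +
    geom_point(alpha = 0.7) +
    labs(
      x = "PLS1 regional score",
      y = "response map",
      title = sprintf("component 1 explains %.1f%% of map variance",
                      100 * object$var_explained)
    ) +
    theme_minimal()
}

#' Plot bootstrap gene Z-scores
#'
#' Ranked gene Z-scores with the extraction thresholds marked.
#'
#' @param object a `pls_gene_z` table.
#' @param z_threshold threshold drawn as horizontal guides (default 5).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pls_gene_z <- function(object, z_threshold = 5, ...) {
  df <- tibble::as_tibble(object)
  df$rank <- rank(-df$z, ties.method = "first")
  ggplot(df, aes(x = .data$rank, y = .data$z)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_hline(yintercept = c(-z_threshold, z_threshold),
               linetype = 2, colour = "firebrick") +
    labs(x = "gene rank", y = "bootstrap Z") +
    theme_minimal()
}
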