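#' Plot a GSEA running enrichment profile
#'
#' @param object A `gsea_result`.
#' @param ... Ignored.
#' @return A ggplot: the running enrichment score with hit positions as a
#'   rug and the ES marked.
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- tidy(object)
  es_pos <- which.max(abs(object$running_profile))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$running_es)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(data = df[df$is_hit, ], sides = "b",
                      length = ggplot2::unit(0.03, "npc")) +
    ggplot2::annotate("point", x = es_pos, y = object$ES,
                      colour = "#d95f02") +
    ggplot2::labs(x = "Rank in ordered list",
                  y = "Running enrichment score",
                  title = sprintf("ES = %.3f, p = %.3g", object$ES,
                                  object$nominal_p)) +
    ggplot2::theme_minimal()
}

#' Plot a concordance-at-the-top curve
#'
#' @param object A `cat_curve` tibble (or several row-bound together with
#'   a `comparison` column).
#' @param ... Ignored.
#' @return A ggplot of shared-gene proportion against list size.
#' @export
autoplot.cat_curve <- function(object, ...) {
  aes <- if ("comparison" %in% names(object)) {
    ggplot2::aes(x = .data$n, y = .data$concordance,
                 colour = .data$comparison)
  } else {
    ggplot2::aes(x = .data$n, y = .data$concordance)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Top-n list size", y = "Proportion shared") +
    ggplot2::theme_minimal()
}

#' Plot a pathway-interconnectivity network
#'
#' Nodes are significant pathways (size = number of regulated genes,
#' colour = weighted connectivity); edge width is the number of shared
#' regulated genes.
#'
#' @param object A `pathway_network`.
#' @param seed Layout seed.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pathway_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  lay <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes
  nodes$x <- lay[, 1]; nodes$y <- lay[, 2]
  edges <- object$edges
  if (nrow(edges)) {
    ei <- match(edges$from, nodes$pathway_id)
    ej <- match(edges$to, nodes$pathway_id)
    edf <- tibble::tibble(x = nodes$x[ei], y = nodes$y[ei],
                          xend = nodes$x[ej], yend = nodes$y[ej],
                          shared = edges$shared)
  } else {
    edf <- tibble::tibble(x = numeric(), y = numeric(), xend = numeric(),
                          yend = numeric(), shared = integer())
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edf,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend,
                                       linewidth = .data$shared),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$n_regulated,
                                     colour = .data$connections)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$pathway_id),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::scale_colour_gradient(low = "white", high = "red") +
    ggplot2::theme_void()
}

#' Scatter plot of tag versus array log2ratios by detection level
#'
#' @param dge,array_mean,gene_counts,threshold As in
#'   [stratified_correlation()].
#' @return A ggplot colouring genes by whether they reach the detection
#'   threshold.
#' @export
plot_detection_correlation <- function(dge, array_mean, gene_counts,
                                       threshold = 32L) {
  cnt <- as.matrix(gene_counts[, count_cols(gene_counts)])
  lvl <- tibble::tibble(
    gene_symbol = gene_counts$gene_symbol,
    above = apply(cnt >= threshold, 1, any),
    detected = rowSums(cnt) > 0)
  df <- tibble::tibble(
    gene_symbol = dge$gene_symbol,
    dge = rowMeans(as.matrix(dge[, value_cols(dge)]), na.rm = TRUE)) |>
    dplyr::inner_join(
      tibble::tibble(
        gene_symbol = array_mean$gene_symbol,
        array = rowMeans(as.matrix(array_mean[, value_cols(array_mean)]),
                         na.rm = TRUE)),
      by = "gene_symbol") |>
    dplyr::inner_join(lvl, by = "gene_symbol") |>
    dplyr::filter(.data$detected)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$array, y = .data$dge,
                                   colour = .data$above)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#1b9e77", `FALSE` = "grey40"),
      name = sprintf(">= %d counts", threshold)) +
    ggplot2::labs(x = "Mean microarray log2ratio", y = "DGE log2ratio") +
    ggplot2::theme_minimal()
}
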