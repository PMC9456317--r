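#' Loading-space plot of samples
#'
#' Projects samples onto two components of the loading space, colored by
#' phenotype and shaped by cell line — the visual check that one component
#' separates the PKH26+ and PKH26- samples by loading sign.
#'
#' @param pca a `quiescr_pca`.
#' @param design design tibble.
#' @param components length-2 integer vector of component indices.
#' @return a ggplot.
#' @export
plot_loading_space <- function(pca, design, components = c(2, 3)) {
  L <- pca$eigenvectors
  df <- tibble(sample = rownames(L),
               x = L[, components[1L]], y = L[, components[2L]]) |>
    left_join(design, by = "sample")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   color = .data$phenotype,
                                   shape = .data$line)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey70") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = sprintf("PC%d loading", components[1L]),
                  y = sprintf("PC%d loading", components[2L])) +
    ggplot2::theme_minimal()
}

#' @method autoplot quiescr_pca
#' @export
autoplot.quiescr_pca <- function(object, ...) {
  df <- variance_table(object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Component", y = "Proportion of variance") +
    ggplot2::theme_minimal()
}

#' Mean-difference (MD) plot
#'
#' Average log-CPM against logFC, with the top/bottom ranked blocks
#' highlighted.
#'
#' @param de a `quiescr_de` tibble.
#' @param ranks optional list from [rank_top_bottom()].
#' @return a ggplot.
#' @export
plot_md <- function(de, ranks = NULL) {
  df <- mutate(de, membership = "other")
  if (!is.null(ranks)) {
    df <- mutate(df, membership = dplyr::case_when(
      .data$gene %in% ranks$up$gene ~ "up",
      .data$gene %in% ranks$down$gene ~ "down",
      TRUE ~ "other"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$aveExpr, .data$logFC,
                                   color = .data$membership)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(up = "firebrick",
                                           down = "royalblue",
                                           other = "grey60")) +
    ggplot2::labs(x = "Average log-CPM", y = "logFC (PKH26+ - PKH26-)") +
    ggplot2::theme_minimal()
}

#' Running-sum enrichment plot
#'
#' @param es result of [enrichment_score()].
#' @return a ggplot.
#' @export
plot_running_sum <- function(es) {
  ggplot2::ggplot(es$curve, ggplot2::aes(.data$position, .data$running)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_line(color = "darkgreen") +
    ggplot2::geom_rug(data = filter(es$curve, .data$hit),
                      sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "Rank", y = "Running enrichment score") +
    ggplot2::theme_minimal()
}

#' Betweenness rewiring scatter
#'
#' Betweenness in the PKH26+ network against the PKH26- network; genes whose
#' rank shifts most between states are highlighted.
#'
#' @param rewiring a tibble from [rewiring_report()].
#' @return a ggplot.
#' @export
plot_rewiring <- function(rewiring) {
  ggplot2::ggplot(rewiring, ggplot2::aes(.data$betweenness_plus,
                                         .data$betweenness_minus,
                                         color = .data$flagged)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey70") +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey50")) +
    ggplot2::labs(x = "Betweenness (PKH26+)", y = "Betweenness (PKH26-)",
                  color = "Rewired") +
    ggplot2::theme_minimal()
}

#' Clustering-coefficient / betweenness space
#'
#' @param centrality joined centrality tibble with `betweenness` and
#'   `clustering` columns (see the pipeline's `centrality` element).
#' @param highlight optional gene ids drawn in blue.
#' @return a ggplot.
#' @export
plot_centrality_space <- function(centrality, highlight = NULL) {
  df <- mutate(centrality,
               highlighted = .data$gene %in% (highlight %||% character(0)))
  ggplot2::ggplot(df, ggplot2::aes(.data$clustering, .data$betweenness,
                                   color = .data$highlighted)) +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "royalblue",
                                           `FALSE` = "grey40")) +
    ggplot2::labs(x = "Clustering coefficient", y = "Betweenness") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
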