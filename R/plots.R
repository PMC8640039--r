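#' Volcano plot of classified differential records
#'
#' @param records Output of [classify_differential()].
#' @param p_alpha Horizontal significance line.
#' @return A ggplot; point size maps VIP when present.
#' @export
plot_volcano <- function(records, p_alpha = 0.05) {
  aes_args <- ggplot2::aes(x = .data$log2FC, y = -log10(.data$p_value),
                           colour = .data$trend)
  g <- ggplot2::ggplot(records, aes_args)
  g <- if ("vip" %in% names(records)) {
    g + ggplot2::geom_point(ggplot2::aes(size = .data$vip), alpha = 0.6)
  } else {
    g + ggplot2::geom_point(alpha = 0.6)
  }
  g +
    ggplot2::geom_hline(yintercept = -log10(p_alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(up = "#d73027", down = "#4575b4", none = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 P", colour = NULL,
                  size = "VIP") +
    ggplot2::theme_minimal()
}

#' z-score plot of a biomarker panel against the control group
#'
#' @param table Feature table of intensities.
#' @param metadata Sample metadata.
#' @param features Feature ids of the panel.
#' @param control,treatment Group labels.
#' @return A ggplot of per-sample z-scores by metabolite.
#' @export
plot_zscores <- function(table, metadata, features, control, treatment) {
  md <- metadata[metadata$group %in% c(control, treatment) &
                   metadata$sample_id %in% sample_cols(table), ]
  tab <- table[table$feature_id %in% features, ]
  m <- ft_matrix(tab, md$sample_id)
  ctl <- md$sample_id[md$group == control]
  z <- t(apply(m, 1, function(v) zscore_vs_control(v, v[colnames(m) %in% ctl])))
  df <- tibble::as_tibble(z, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id", values_to = "z") |>
    dplyr::left_join(md, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$feature_id,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "z-score vs control", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a significance-masked correlation matrix
#'
#' Pairs whose correlation test exceeded the mask level are blanked, matching
#' the convention of masked biomarker correlation heatmaps.
#'
#' @param corr A [correlation_matrix()] result.
#' @return A ggplot tile heatmap.
#' @export
plot_correlation <- function(corr) {
  if (!inherits(corr, "sbmie_corr")) abort("`corr` must come from correlation_matrix()")
  r <- corr$r
  r[corr$mask] <- NA
  df <- tibble::as_tibble(r, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "r") |>
    dplyr::mutate(row = factor(.data$row, levels = rownames(corr$r)),
                  col = factor(.data$col, levels = colnames(corr$r)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$r)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "#4575b4", mid = "white",
                                  high = "#d73027", limits = c(-1, 1),
                                  na.value = "grey92") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0("r (blank: P > ", corr$alpha, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_correlation
#' @param object A `sbmie_corr` object.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot sbmie_corr
#' @export
autoplot.sbmie_corr <- function(object, ...) plot_correlation(object)

#' Alpha-diversity boxplots by group
#'
#' @param alpha Output of [alpha_diversity_table()] joined with metadata (must
#'   carry a `group` column).
#' @param indices Index columns to show.
#' @return A ggplot with one panel per index.
#' @export
plot_alpha_diversity <- function(alpha, indices = c("s_obs", "shannon",
                                                    "simpson", "chao1", "ace")) {
  if (!"group" %in% names(alpha)) abort("`alpha` must carry a `group` column")
  df <- tidyr::pivot_longer(alpha, dplyr::all_of(indices),
                            names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
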