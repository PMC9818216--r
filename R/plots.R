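#' Alpha-diversity boxplots by cohort
#'
#' @param alpha Tibble from [alpha_diversity()] including a `cohort` column.
#' @param indices Which indices to facet (default all five).
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(alpha,
                                 indices = c("observed", "shannon", "simpson",
                                             "chao1", "ace")) {
  stopifnot("cohort" %in% names(alpha))
  long <- tidyr::pivot_longer(alpha, dplyr::all_of(indices),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cohort, y = .data$value,
                                     fill = .data$cohort)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, alpha = 0.8) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Ordination plot for a PCoA result
#'
#' @param object A `pcoa_result`.
#' @param metadata Optional metadata tibble; points are coloured by cohort.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_result <- function(object, metadata = NULL, ...) {
  df <- tidy(object)
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df,
                           dplyr::select(validate_metadata(metadata),
                                         "sample_id", "cohort"),
                           by = "sample_id")
  }
  pct <- round(100 * object$explained_fraction[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pct[1]),
                  y = sprintf("PCo2 (%.1f%%)", pct[2])) +
    ggplot2::theme_bw()
  if ("cohort" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cohort), size = 2) +
      ggplot2::stat_ellipse(ggplot2::aes(colour = .data$cohort),
                            show.legend = FALSE)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' LDA effect-size histogram
#'
#' Horizontal bars of biomarker scores by winning class, the conventional
#' rendering of LEfSe output.
#'
#' @param lefse_result Tibble from [lefse()].
#' @param threshold Score line to draw (default 3).
#' @return A ggplot object.
#' @export
plot_lda_scores <- function(lefse_result, threshold = 3) {
  df <- dplyr::filter(lefse_result, !is.na(.data$lda_score))
  df <- dplyr::arrange(df, .data$class, .data$lda_score)
  df$feature_id <- factor(df$feature_id, levels = df$feature_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lda_score, y = .data$feature_id,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "LDA score (log10)", y = NULL, fill = "Enriched in") +
    ggplot2::theme_bw()
}

#' Draw one correlation star network
#'
#' Neighbors are placed on a circle around the center; edge colour encodes
#' the correlation sign, width its magnitude.
#'
#' @param stars Tibble from [extract_stars()].
#' @param center Center feature id to draw (default: first row).
#' @return A ggplot object.
#' @export
plot_star <- function(stars, center = NULL) {
  if (nrow(stars) == 0) stop("no stars to plot", call. = FALSE)
  if (is.null(center)) center <- stars$center[1]
  row <- stars[stars$center == center, ]
  if (nrow(row) == 0) stop("no star centered on '", center, "'", call. = FALSE)
  inc <- row$neighbors[[1]]
  other <- ifelse(inc$feature_a == center, inc$feature_b, inc$feature_a)
  other_layer <- ifelse(inc$feature_a == center, inc$layer_b, inc$layer_a)
  k <- length(other)
  theta <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  nodes <- tibble::tibble(
    feature = c(center, other),
    layer = c(row$center_layer[1], other_layer),
    x = c(0, cos(theta)), y = c(0, sin(theta))
  )
  segs <- tibble::tibble(x = 0, y = 0, xend = cos(theta), yend = sin(theta),
                         r = inc$r)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$r > 0,
                   linewidth = abs(.data$r))
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$layer), size = 4
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x * 1.15, y = .data$y * 1.15,
                   label = .data$feature), size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "#0072B2"),
                                 labels = c(`TRUE` = "r > 0",
                                            `FALSE` = "r < 0")) +
    ggplot2::scale_linewidth(range = c(0.3, 1.6), guide = "none") +
    ggplot2::labs(colour = NULL, shape = "Layer",
                  title = paste("Network centered on", center)) +
    ggplot2::theme_void()
}
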