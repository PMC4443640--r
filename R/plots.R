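# ggplot2 views of the pipeline's result tables.

#' Plot transcript structure with binding-site locations
#'
#' Draws each transcript as its 5'UTR/CDS/3'UTR boxes in transcript
#' coordinates with the miR156 binding sites as vertical dashed lines,
#' mirroring the classic gene-structure figure of family surveys.
#'
#' @param partitions Tibble from [region_partition()].
#' @param sites Located sites tibble (needs `transcript_id`, `start`).
#' @return A ggplot object.
#' @export
plot_gene_structure <- function(partitions, sites = NULL) {
  partitions$transcript_id <- factor(partitions$transcript_id)
  p <- ggplot2::ggplot(partitions) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = as.integer(.data$transcript_id) - 0.3,
      ymax = as.integer(.data$transcript_id) + 0.3,
      fill = .data$region), colour = "grey20", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(
      FIVE_UTR = "white", CDS = "grey60", THREE_UTR = "white",
      NONCODING = "grey90")) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(partitions$transcript_id)),
      labels = levels(partitions$transcript_id)) +
    ggplot2::labs(x = "transcript position (nt)", y = NULL,
                  fill = "region") +
    ggplot2::theme_minimal()
  if (!is.null(sites) && nrow(sites) > 0) {
    sites$y <- as.integer(factor(sites$transcript_id,
                                 levels = levels(partitions$transcript_id)))
    p <- p + ggplot2::geom_segment(
      data = sites,
      ggplot2::aes(x = .data$start, xend = .data$start,
                   y = .data$y - 0.42, yend = .data$y + 0.42),
      linetype = "dashed", colour = "red")
  }
  p
}

#' Plot TMM normalization factors
#'
#' @param factors Tibble from [tmm_factors()].
#' @return A ggplot object.
#' @export
plot_tmm_factors <- function(factors) {
  ggplot2::ggplot(factors, ggplot2::aes(x = .data$sample, y = .data$factor)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "TMM scaling factor") +
    ggplot2::theme_minimal()
}

#' Plot relative expression with significance letters
#'
#' Bars of group-level relative units (RU) per gene; letters above bars
#' mark Tukey-Kramer groupings when supplied.
#'
#' @param ru Tibble from [relative_expression()].
#' @param letters Optional tibble with `gene`, `group`, `letter`.
#' @return A ggplot object.
#' @export
plot_relative_expression <- function(ru, letters = NULL) {
  df <- ru
  if (!is.null(letters)) {
    df <- dplyr::left_join(df, letters, by = c("gene", "group"))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$ru)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative expression (RU)") +
    ggplot2::theme_minimal()
  if (!is.null(letters)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$letter),
                                vjust = -0.4, na.rm = TRUE)
  }
  p
}

#' Autoplot method for Tukey-Kramer fits
#'
#' Group means with compact letter display.
#'
#' @param object An `spl_anova` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot spl_anova
autoplot.spl_anova <- function(object, ...) {
  df <- object$letters
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "group mean",
                  subtitle = sprintf("F(%d, %d) = %.3g, p = %.3g",
                                     object$df[1], object$df[2],
                                     object$f, object$p)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
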