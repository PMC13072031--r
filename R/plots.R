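# ggplot2 views of the main result types. Numbers, not figures, are the
# analytical surface; these are convenience displays.

#' @exportS3Method ggplot2::autoplot
autoplot.gated_comparison <- function(object, ...) {
  means <- left_join(object$group_means, object$letters, by = "group")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                       vjust = -0.5, size = 4) +
    ggplot2::labs(x = NULL, y = "group mean",
                  subtitle = sprintf("%s; groups sharing a letter do not differ at alpha = %g",
                                     object$omnibus$method, object$alpha)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ratio_pca <- function(object, colour = NULL, ...) {
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour) && colour %in% names(sc)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else if (all(c("condition", "position") %in% names(sc))) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = interaction(.data$condition, .data$position)),
      size = 2) +
      ggplot2::labs(colour = "group")
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  arrows <- object$loadings |>
    mutate(xend = .data$PC1 * 2, yend = .data$PC2 * 2)
  p +
    ggplot2::geom_segment(data = arrows,
                          ggplot2::aes(x = 0, y = 0, xend = .data$xend,
                                       yend = .data$yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "grey40") +
    ggplot2::geom_text(data = arrows,
                       ggplot2::aes(x = .data$xend * 1.1, y = .data$yend * 1.1,
                                    label = .data$ratio), colour = "grey20") +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-condition resorption efficiencies
#'
#' @param report An [run_analysis()] result.
#' @return A ggplot object.
#' @export
plot_resorption <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  d <- report$resorption |>
    tidyr::pivot_longer(c("nre_n", "nre_p"), names_to = "nutrient",
                        values_to = "nre") |>
    mutate(nutrient = toupper(sub("nre_", "", .data$nutrient)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nutrient, y = .data$nre,
                                  fill = .data$condition)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.8), shape = 21) +
    ggplot2::labs(x = NULL, y = "nutrient resorption efficiency (%)") +
    ggplot2::theme_minimal()
}

#' Heatmap of the needle-soil stoichiometric deviation grid
#'
#' @param report An [run_analysis()] result.
#' @param convention SDI convention to display.
#' @return A ggplot object.
#' @export
plot_sdi_grid <- function(report, convention = "group_mean") {
  stopifnot(inherits(report, "analysis_report"))
  d <- filter(report$sdi_grid, .data$convention == !!convention)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$soil_layer,
                                  fill = .data$sdi)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$sdi)), size = 3) +
    ggplot2::facet_wrap(~ .data$ratio) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "needle group", y = "soil layer (cm)", fill = "SDI") +
    ggplot2::theme_minimal()
}

#' Heatmap of the needle-soil correlation grid
#'
#' @param report An [run_analysis()] result.
#' @return A ggplot object.
#' @export
plot_correlation_grid <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  d <- mutate(report$correlations,
              significant = !is.na(.data$p_value) & .data$p_value < 0.05)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$soil_layer,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$p_value), "",
                                                   sprintf("%.2f", .data$p_value)),
                                    fontface = ifelse(.data$significant, "bold", "plain")),
                       size = 3) +
    ggplot2::facet_wrap(~ .data$ratio) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "needle group", y = "soil layer (cm)", fill = "Pearson r") +
    ggplot2::theme_minimal()
}
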