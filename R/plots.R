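# Plot helpers for ion images, zonal profiles and test summaries.

#' Ion image of one feature
#'
#' @param fm A `feature_matrix`.
#' @param feature_id Feature id, or `mz` to select the nearest feature.
#' @param mz Optional target m/z.
#' @param mouse Mouse to display (default first).
#' @return A ggplot object.
#' @export
plot_ion_image <- function(fm, feature_id = NULL, mz = NULL, mouse = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(feature_id)) {
    stopifnot(!is.null(mz))
    feature_id <- fm$features$feature_id[which.min(abs(fm$features$mz - mz))]
  }
  j <- match(feature_id, fm$features$feature_id)
  stopifnot(!is.na(j))
  d <- fm$pixels
  d$intensity <- fm$values[, j]
  if ("mouse" %in% names(d)) {
    if (is.null(mouse)) mouse <- d$mouse[1]
    d <- d[d$mouse == mouse, ]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "intensity") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("m/z %.4f", fm$features$mz[j]),
      x = "column", y = "row"
    ) +
    ggplot2::theme_minimal()
}

#' Zonal intensity profiles of selected lipids
#'
#' ROI medians by zone, one panel per lipid.
#'
#' @param table Zonal long table from [extract_roi_medians()].
#' @param lipids Lipid ids to show.
#' @return A ggplot object.
#' @export
plot_zone_profiles <- function(table, lipids) {
  d <- table[table$lipid_id %in% lipids, ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$zone, y = .data$median_intensity,
    colour = .data$zone
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::facet_wrap(~lipid_id, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(
      Z1 = "#c0392b", Z2 = "#f1c40f",
      Z3 = "#2980b9"
    )) +
    ggplot2::labs(x = "zone", y = "ROI median intensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @method autoplot zonation_test
#' @export
autoplot.zonation_test <- function(object, ...) {
  d <- object[object$significant, ]
  d$dominant_zone <- factor(d$dominant_zone, levels = c("Z1", "Z2", "Z3"))
  x <- if ("lipid_class" %in% names(d)) "lipid_class" else "dominant_zone"
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[x]], fill = .data$dominant_zone)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(
      values = c(Z1 = "#c0392b", Z2 = "#f1c40f", Z3 = "#2980b9"),
      name = "dominant zone", drop = FALSE
    ) +
    ggplot2::labs(
      x = NULL, y = "significant lipids",
      title = "Zonation of significant lipids"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot pathway_ranking
#' @export
autoplot.pathway_ranking <- function(object, top = 10, ...) {
  d <- utils::head(object, top)
  d$pathway <- factor(d$pathway, levels = rev(d$pathway))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$pathway)) +
    ggplot2::geom_col(fill = "#2c3e50") +
    ggplot2::labs(
      x = "centrality-weighted pathway score", y = NULL,
      title = "Top-ranked pathways"
    ) +
    ggplot2::theme_minimal()
}
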