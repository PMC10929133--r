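#' Plot per-tooth RBL with stage bands
#'
#' Bar chart of RBL% by tooth, filled by assigned stage, with horizontal
#' lines at the stage cut-offs.
#'
#' @param object An `rbl_analysis` from [measure_dentition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rbl_analysis <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$tooth_number),
                                   y = .data$rbl_percent, fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$thresholds, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_fill_manual(
      values = c(I = "#4daf4a", II = "#ff7f00", III = "#e41a1c"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "Tooth (universal number)", y = "RBL (%)",
                  fill = "Stage") +
    ggplot2::theme_minimal()
}

#' Plot per-stage report metrics
#'
#' Dot plot of precision / sensitivity / F1 / specificity per stage (macro
#' row included), faceted by method when several reports are bound together.
#'
#' @param object A `stage_report` from [stage_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stage_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("precision", "sensitivity", "f1", "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$value,
                                     colour = .data$metric, group = .data$metric)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$method)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Stage", y = "Value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay a tooth's regions, principal axis and hulls
#'
#' Diagnostic view of one measurement: region pixels as a raster (crown,
#' suprabony, intrabony), the convex hulls of the suprabony and whole-root
#' regions, and the clipped principal-axis segment used for the A/B lengths.
#'
#' @param tooth A [tooth_region_mask()].
#' @param axis_source Passed to [rbl_geometry()].
#' @return A ggplot object.
#' @export
plot_tooth_measurement <- function(tooth, axis_source = "tooth") {
  geom <- rbl_geometry(tooth, axis_source = axis_source)
  region_df <- function(mask, name) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    tibble::tibble(row = idx[, 1], col = idx[, 2], region = name)
  }
  px <- dplyr::bind_rows(
    region_df(tooth$crown, "crown"),
    region_df(tooth$suprabony, "suprabony"),
    region_df(tooth$intrabony, "intrabony")
  )
  hull_df <- function(hull, name) {
    if (is.null(hull)) return(NULL)
    v <- hull$vertices
    tibble::tibble(row = c(v[, 1], v[1, 1]), col = c(v[, 2], v[1, 2]), hull = name)
  }
  hulls <- dplyr::bind_rows(hull_df(geom$hull_supra, "suprabony hull"),
                            hull_df(geom$hull_root, "root hull"))
  half <- geom$b / 2 + 5
  seg <- tibble::tibble(
    row0 = geom$axis$centroid[1] - half * geom$axis$direction[1],
    col0 = geom$axis$centroid[2] - half * geom$axis$direction[2],
    row1 = geom$axis$centroid[1] + half * geom$axis$direction[1],
    col1 = geom$axis$centroid[2] + half * geom$axis$direction[2]
  )
  p <- ggplot2::ggplot(px, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$region)) +
    ggplot2::scale_fill_manual(values = c(
      crown = "#cbd5e8", suprabony = "#fdcdac", intrabony = "#b3e2cd"
    )) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col", y = "row", fill = "Region", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(hulls) && nrow(hulls) > 0L) {
    p <- p + ggplot2::geom_path(
      data = hulls, ggplot2::aes(group = .data$hull, colour = .data$hull),
      linewidth = 0.6
    )
  }
  p + ggplot2::geom_segment(
    data = seg,
    ggplot2::aes(x = .data$col0, y = .data$row0, xend = .data$col1, yend = .data$row1),
    colour = "navy", linewidth = 0.8, inherit.aes = FALSE
  )
}
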