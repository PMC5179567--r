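# ggplot2 visualisations for the main result types.

#' Zone-count bar plot
#'
#' Cells per concentric zone, faceted by session day: the zonal
#' infiltration pattern around the optic nerve head.
#'
#' @param zone_tbl Output of [zone_counts()] (with a `day` column).
#' @return A ggplot.
#' @export
plot_zone_counts <- function(zone_tbl) {
  df <- zone_tbl[!is.na(zone_tbl$zone), , drop = FALSE]
  df$zone_label <- paste("Region", as.roman(df$zone))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zone_label, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$day), labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "cells",
                  title = "Zonal cell counts around the optic nerve head") +
    ggplot2::theme_minimal()
}

#' Track overlay plot
#'
#' Planar trajectories coloured by track, with the optic nerve head and the
#' concentric zone boundaries for orientation.
#'
#' @param track_points Output of [link_tracks()].
#' @param zones Optional [zone_config()] to draw the ONH and zone circles.
#' @return A ggplot.
#' @export
plot_tracks <- function(track_points, zones = NULL) {
  p <- ggplot2::ggplot(track_points,
                       ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                    group = .data$cell_id,
                                    colour = factor(.data$cell_id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (um)", y = "y (um)", title = "Cell trajectories") +
    ggplot2::theme_minimal()
  if (!is.null(zones)) {
    th <- seq(0, 2 * pi, length.out = 181)
    circles <- purrr::map(zones$radii, function(r) {
      tibble::tibble(x_um = zones$onh_center_um[1] + r * cos(th),
                     y_um = zones$onh_center_um[2] + r * sin(th),
                     cell_id = -r)
    }) |>
      dplyr::bind_rows()
    p <- p + ggplot2::geom_path(data = circles, colour = "grey50",
                                linetype = 2, show.legend = FALSE)
  }
  p
}

#' FRET ratio time-course plot
#'
#' Mean FRET ratio per ROI (or zone) over the imaging session, with the
#' dysfunction boundary drawn at the ratio corresponding to the calibration
#' threshold.
#'
#' @param time_course Output of [roi_time_course()] (or [zone_fret()], with
#'   a `frame` column used as time when `t_min` is absent).
#' @param cal Optional [fit_calibration()]; draws the dysfunction boundary.
#' @return A ggplot.
#' @export
plot_fret_time_course <- function(time_course, cal = NULL) {
  df <- time_course
  if (!"t_min" %in% names(df)) {
    df$t_min <- df$frame - 1
  }
  grp <- if ("roi" %in% names(df)) "roi" else "zone"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$mean_ratio,
                                        colour = factor(.data[[grp]]))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "FRET ratio", colour = grp) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(cal)) {
    p <- p + ggplot2::geom_hline(
      yintercept = calcium_to_ratio(cal$dysfunction_threshold_M, cal),
      linetype = 2, colour = "red")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Render a FRET map as a ratio image
#'
#' @param object A `fret_map`.
#' @param frame Frame to display (default 1).
#' @param ... Unused.
#' @return A ggplot raster of the FRET ratio.
#' @method autoplot fret_map
#' @export
autoplot.fret_map <- function(object, frame = 1, ...) {
  d <- dim(object$ratio)
  r <- if (length(d) == 3L) object$ratio[, , frame] else object$ratio
  px <- object$voxel_size_um %||% c(1, 1)
  df <- expand.grid(y = pixel_centers(d[1], d[1] * px[2]),
                    x = pixel_centers(d[2], d[2] * px[1]))
  df$ratio <- as.vector(r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$ratio)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "black") +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "FRET ratio") +
    ggplot2::theme_minimal()
}

#' Pairwise comparison plot
#'
#' @param object A [compare_groups()] result.
#' @param ... Unused.
#' @return A ggplot of adjusted p values per pairwise comparison.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- object$pairwise
  df$pair <- paste(df$group1, "vs", df$group2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = -log10(.data$p_adj))) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = NULL, y = "-log10 adjusted p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
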