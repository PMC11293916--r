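#' Plot an oscillogram
#'
#' Endplate index (1 = T1 superior, 34 = L5 inferior) on the x axis, tilt
#' in degrees on the y axis, one panel or colour per view. Detected peaks
#' and troughs can be overlaid by passing the case's measurement.
#'
#' @param object An `oscillogram` tibble (one or more views).
#' @param measurement Optional `case_measurement`; its coronal curve end
#'   endplates are marked.
#' @param min_prominence Prominence used to mark extrema (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oscillogram
#' @export
autoplot.oscillogram <- function(object, measurement = NULL,
                                 min_prominence = 5, ...) {
  osc <- tibble::as_tibble(object)
  ex <- osc |>
    dplyr::group_split(.data$view) |>
    purrr::map(function(sub) {
      e <- find_extrema(sub$tilt[order(sub$endplate)], min_prominence)
      if (nrow(e) > 0) e$view <- sub$view[1]
      e
    }) |>
    dplyr::bind_rows()
  p <- ggplot2::ggplot(osc, ggplot2::aes(x = .data$endplate, y = .data$tilt)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey70") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$view), ncol = 1) +
    ggplot2::scale_x_continuous(
      breaks = seq(1, 33, by = 4),
      labels = paste0(endplate_vertebra(seq(1, 33, by = 4)), "-",
                      endplate_surface(seq(1, 33, by = 4)))) +
    ggplot2::labs(x = "endplate (cranial to caudal)",
                  y = "endplate tilt (degrees)") +
    ggplot2::theme_minimal()
  if (nrow(ex) > 0) {
    p <- p + ggplot2::geom_point(
      data = ex,
      ggplot2::aes(x = .data$endplate, y = .data$tilt,
                   shape = .data$polarity),
      colour = "firebrick", size = 2)
  }
  if (!is.null(measurement)) {
    marks <- measurement$curves |>
      tidyr::pivot_longer(cols = c("upper_endplate", "lower_endplate"),
                          values_to = "endplate")
    marks$view <- "coronal"
    marks <- dplyr::left_join(marks, osc[c("view", "endplate", "tilt")],
                              by = c("view", "endplate"))
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$endplate),
                                 linetype = "dashed", colour = "grey50",
                                 linewidth = 0.3)
  }
  p
}

#' Plot the landmark geometry of a view
#'
#' Draws the vertebral outlines (corner points joined per vertebra) in
#' image coordinates, y axis reversed so the display matches the
#' radiograph orientation.
#'
#' @param lm Landmark tibble (one or more views).
#' @return A ggplot object.
#' @export
plot_landmarks <- function(lm) {
  lm <- tibble::as_tibble(lm)
  # close the box: ul -> ur -> lr -> ll
  path_order <- c(ul = 1L, ur = 2L, lr = 3L, ll = 4L)
  lm$ord <- path_order[lm$corner]
  ggplot2::ggplot(dplyr::arrange(lm, .data$vertebra, .data$ord),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               group = .data$vertebra)) +
    ggplot2::geom_polygon(fill = "grey85", colour = "grey30",
                          linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(ggplot2::vars(.data$view), nrow = 1) +
    ggplot2::labs(x = "x (image)", y = "y (image, down)") +
    ggplot2::theme_minimal()
}
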