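# Quick-look graphics for root systems and sector distributions.

#' Plot a root system (top and side view)
#'
#' Segments coloured by pooled compartment, drawn in the container frame:
#' top view (x-y, perpendicular to the soil surface) and side view (x-z).
#'
#' @param object A [root_system()].
#' @param ... Unused.
#' @return A ggplot (facetted top/side view).
#' @export
autoplot.root_system <- function(object, ...) {
  vsc <- classify_compartments(object)
  seg <- dplyr::left_join(
    object$segments,
    dplyr::summarise(dplyr::group_by(vsc, .data$segment_id),
                     pooled = .data$pooled[1], .groups = "drop"),
    by = "segment_id"
  )
  w <- object$container / 2
  long <- dplyr::bind_rows(
    dplyr::transmute(seg, view = "top (x-y)",
                     x = .data$base_x, y = .data$base_y,
                     xend = .data$tip_x, yend = .data$tip_y,
                     pooled = .data$pooled, diameter = .data$diameter),
    dplyr::transmute(seg, view = "side (x-z)",
                     x = .data$base_x, y = .data$base_z,
                     xend = .data$tip_x, yend = .data$tip_z,
                     pooled = .data$pooled, diameter = .data$diameter)
  )
  frame <- dplyr::bind_rows(
    tibble::tibble(view = "top (x-y)",
                   xmin = -w[1], xmax = w[1], ymin = -w[2], ymax = w[2]),
    tibble::tibble(view = "side (x-z)",
                   xmin = -w[1], xmax = w[1], ymin = -object$container[3], ymax = 0)
  )
  ggplot2::ggplot(long) +
    ggplot2::geom_rect(
      data = frame,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      fill = NA, colour = "grey40", linetype = 2
    ) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$pooled,
                   linewidth = .data$diameter)
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::facet_wrap(~view, scales = "free") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x: north / upslope (m)", y = "m",
                  colour = "compartment",
                  title = sprintf("plant %s", object$plant_id)) +
    ggplot2::theme_minimal()
}

#' Bar chart of sector shares
#'
#' @param ss A [sector_shares()] table.
#' @param var Which share to draw: `"volume_share"`, `"length_share"` or
#'   `"n_share"`.
#' @return A ggplot.
#' @export
plot_sector_shares <- function(ss, var = "volume_share") {
  ss$sector <- factor(ss$sector, levels = c("us", "pp", "ds"))
  ggplot2::ggplot(ss, ggplot2::aes(.data$sector, .data[[var]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = c(25, 50), linetype = 3) +
    ggplot2::facet_wrap(~compartment) +
    ggplot2::labs(y = paste(var, "(%)"),
                  x = "sector (us = upslope, pp = perpendicular, ds = downslope)") +
    ggplot2::theme_minimal()
}
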