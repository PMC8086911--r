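#' Dashed radiance guide levels for the standard chart
#'
#' Indicative lit levels drawn as dashed lines in the main chart panel.
#' They are arbitrary orientation marks, not measurements, and are fully
#' configurable.
#'
#' @return A tibble with columns `label` and `lit`.
#' @export
guide_levels <- function() {
  tibble(
    label = c("starlight", "moonlight", "twilight", "overcast", "sunlight"),
    lit = c(9, 11, 13, 15.5, 17)
  )
}

band_colours <- c(white = "black", red = "#cc3333", green = "#2e8b2e",
                  blue = "#2255cc")

#' Main radiance-versus-elevation panel
#'
#' Median lit curves for the red, green, blue and white bands against
#' elevation angle, with the white-band 50% (dark grey) and 95% (light
#' grey) contrast-span envelopes and dashed guide levels. All numbers are
#' read from the statistics table; nothing is recomputed from pixels.
#'
#' @param stats An `elf_stats` tibble.
#' @param guides Guide-level tibble as from [guide_levels()], or NULL.
#' @return A ggplot object with lit on x and elevation on y.
#' @export
plot_radiance_profile <- function(stats, guides = guide_levels()) {
  long <- tidy(stats)
  med <- dplyr::filter(long, .data$statistic == "median")
  p <- ggplot2::ggplot(stats, ggplot2::aes(y = .data$elevation)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(xmin = .data$white_p2_5, xmax = .data$white_p97_5),
      fill = "grey85", orientation = "y"
    ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(xmin = .data$white_p25, xmax = .data$white_p75),
      fill = "grey65", orientation = "y"
    )
  if (!is.null(guides)) {
    p <- p + ggplot2::geom_vline(
      data = guides, ggplot2::aes(xintercept = .data$lit),
      linetype = "dashed", colour = "grey50", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_path(
      data = med,
      ggplot2::aes(x = .data$value, y = .data$elevation,
                   colour = .data$band),
      linewidth = 0.6
    ) +
    ggplot2::scale_colour_manual(values = band_colours, guide = "none") +
    ggplot2::scale_y_continuous(limits = c(-90, 90),
                                breaks = seq(-90, 90, 30)) +
    ggplot2::labs(x = "radiance (lit)", y = "elevation (°)") +
    ggplot2::theme_bw()
}

#' Normalised colour panel
#'
#' Per-band median minus the white-band median, in lit, against
#' elevation: isolates the spectral balance from the absolute radiance.
#'
#' @inheritParams plot_radiance_profile
#' @return A ggplot object.
#' @export
plot_colour_balance <- function(stats) {
  df <- purrr::map_dfr(c("red", "green", "blue"), function(bn) {
    tibble(
      elevation = stats$elevation, band = bn,
      delta = stats[[paste0(bn, "_median")]] - stats$white_median
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$elevation,
                                   colour = .data$band)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60",
                        linewidth = 0.3) +
    ggplot2::geom_path(linewidth = 0.5) +
    ggplot2::scale_colour_manual(values = band_colours, guide = "none") +
    ggplot2::scale_y_continuous(limits = c(-90, 90),
                                breaks = seq(-90, 90, 45)) +
    ggplot2::labs(x = "colour (lit vs white)", y = NULL) +
    ggplot2::theme_bw()
}

#' Normalised contrast-span panel
#'
#' White-band 50% and 95% contrast-span widths (lit) against elevation.
#'
#' @inheritParams plot_radiance_profile
#' @return A ggplot object.
#' @export
plot_contrast_span <- function(stats) {
  spans <- dplyr::bind_rows(
    dplyr::mutate(contrast_span(stats, 50), level = "50%"),
    dplyr::mutate(contrast_span(stats, 95), level = "95%")
  )
  spans <- dplyr::filter(spans, .data$band == "white")
  ggplot2::ggplot(spans, ggplot2::aes(x = .data$span, y = .data$elevation,
                                      linetype = .data$level)) +
    ggplot2::geom_path(linewidth = 0.5, colour = "grey20") +
    ggplot2::scale_linetype_manual(values = c(`50%` = "solid",
                                              `95%` = "dashed"),
                                   guide = "none") +
    ggplot2::scale_y_continuous(limits = c(-90, 90),
                                breaks = seq(-90, 90, 45)) +
    ggplot2::labs(x = "contrast-span (lit)", y = NULL) +
    ggplot2::theme_bw()
}

# Laterally compressed scene/average image panel.
plot_scene_image <- function(image, compress = 4) {
  tm <- tonemap_image(image, max_size = 256)
  raster <- grDevices::rgb(tm[, , 1], tm[, , 2], tm[, , 3])
  dim(raster) <- dim(tm)[1:2]
  ggplot2::ggplot() +
    ggplot2::annotation_raster(raster, xmin = 0, xmax = 90 / compress * 2,
                               ymin = -90, ymax = 90) +
    ggplot2::scale_y_continuous(limits = c(-90, 90),
                                breaks = seq(-90, 90, 30)) +
    ggplot2::scale_x_continuous(limits = c(0, 90 / compress * 2),
                                breaks = NULL) +
    ggplot2::labs(x = NULL, y = "elevation (°)") +
    ggplot2::theme_bw()
}

#' The standard four-panel chart
#'
#' Assembles the standard graphic: (i) the laterally compressed remapped
#' (or average) image, (ii) the main radiance-versus-elevation diagram
#' with median curves per band and the white 50%/95% contrast-span
#' envelopes, (iii) the normalised colour panel and (iv) the normalised
#' contrast-span panel, in a landscape layout sized so two charts fit an
#' A4 page. All plotted numbers come from the statistics table.
#'
#' @param x An `elf_scene`, environment result, or `elf_stats` (in which
#'   case the image panel is omitted unless `image` is given).
#' @param image Optional [equirect_image()] for the image panel.
#' @param title Chart title; defaults to a stored name if present.
#' @param guides Guide levels as from [guide_levels()], or NULL.
#' @return A patchwork object (renders as the four-panel chart).
#' @export
elf_chart <- function(x, image = NULL, title = NULL, guides = guide_levels()) {
  stats <- if (inherits(x, "elf_stats")) x else x$stats
  if (is.null(image) && !inherits(x, "elf_stats")) image <- x$image
  if (is.null(title)) {
    title <- attr(stats, "name") %||%
      (if (!inherits(x, "elf_stats")) x$name else NULL) %||% ""
  }
  n_scenes <- attr(stats, "n_scenes") %||% 1L
  main <- plot_radiance_profile(stats, guides = guides)
  right <- patchwork::wrap_plots(plot_colour_balance(stats),
                                 plot_contrast_span(stats), ncol = 1)
  if (!is.null(image)) {
    panels <- list(plot_scene_image(image), main, right)
    widths <- c(1.2, 3, 1.4)
  } else {
    panels <- list(main, right)
    widths <- c(3, 1.4)
  }
  patchwork::wrap_plots(panels, nrow = 1) +
    patchwork::plot_layout(widths = widths) +
    patchwork::plot_annotation(
      title = title,
      subtitle = sprintf("%d scene(s) | generated %s", n_scenes,
                         format(Sys.time(), "%Y-%m-%d %H:%M"))
    )
}

#' Save a chart as editable PDF plus small PNG
#'
#' Writes the chart in landscape format at half-A4 print size (editable
#' vector PDF) and as a small raster preview.
#'
#' @param chart A ggplot/patchwork object, e.g. from [elf_chart()].
#' @param pdf_path,png_path Output paths; either may be NULL to skip.
#' @return Invisibly, the paths written.
#' @export
save_chart <- function(chart, pdf_path = NULL, png_path = NULL) {
  written <- character(0)
  if (!is.null(pdf_path)) {
    ggplot2::ggsave(pdf_path, chart, width = 10, height = 4.5,
                    device = grDevices::pdf)
    written <- c(written, pdf_path)
  }
  if (!is.null(png_path)) {
    ggplot2::ggsave(png_path, chart, width = 10, height = 4.5, dpi = 90,
                    device = grDevices::png, bg = "white")
    written <- c(written, png_path)
  }
  invisible(written)
}

#' @describeIn elf_chart autoplot method for `elf_stats`
#' @param object,... Passed to `elf_chart()`.
#' @method autoplot elf_stats
#' @export
autoplot.elf_stats <- function(object, ...) {
  elf_chart(object, ...)
}
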