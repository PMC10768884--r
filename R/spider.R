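#' Spider-plot layout for bilateral tract Z-scores
#'
#' Display conventions for the radar display of per-tract Z-scores: the
#' corpus callosum sits at the top centre and is drawn on both hemisphere
#' layers; the outer solid ring is the control mean (z = 0) with solid
#' grey guide rings at -1, -2, -3, -4 and a dotted ring at the -1.96
#' abnormality threshold; the left-hemisphere polygon is blue, the
#' right-hemisphere polygon red; tract labels are bold when either
#' hemisphere falls below the threshold; z-scores below `clamp_min` are
#' clamped inward with a marker and positive z is clamped to the outer
#' ring.
#'
#' @param tract_order Bundle labels in display order (first = top centre).
#' @param rings Guide-ring z-levels, strictly decreasing toward the
#'   centre.
#' @param dotted_ring Z-level of the dotted threshold ring.
#' @param layer_colors Named colours for the `left` and `right` layers.
#' @param clamp_min Innermost displayable z.
#' @param bold_threshold Bold tract labels when min(z) over hemispheres is
#'   below this.
#' @return An object of class `spider_layout`.
#' @export
spider_layout <- function(tract_order = c("CC", "AF", "CG", "CST", "FX",
                                          "IFOF", "ILF", "SCP", "SLF_I",
                                          "SLF_II", "SLF_III", "UF"),
                          rings = c(0, -1, -2, -3, -4),
                          dotted_ring = -1.96,
                          layer_colors = c(left = "#2166ac",
                                           right = "#b2182b"),
                          clamp_min = -4, bold_threshold = -1.96) {
  if (any(diff(rings) >= 0)) {
    abort_fixelnorm("rings must strictly decrease toward the centre",
                    "fixelnorm_layout_error")
  }
  if (!(dotted_ring < max(rings) && dotted_ring > clamp_min)) {
    abort_fixelnorm(
      "dotted ring must lie strictly between the outer ring and clamp_min",
      "fixelnorm_layout_error")
  }
  structure(list(tract_order = tract_order, rings = rings,
                 dotted_ring = dotted_ring, layer_colors = layer_colors,
                 clamp_min = clamp_min, bold_threshold = bold_threshold),
            class = "spider_layout")
}

#' Read a spider layout from a YAML file
#'
#' @param path YAML file whose keys mirror the [spider_layout()]
#'   arguments.
#' @return A `spider_layout`.
#' @export
read_spider_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(spider_layout, cfg)
}

# bundle label + hemisphere for each tract in a z_report
.spider_data <- function(report, layout) {
  scores <- report$scores
  bundle <- sub("_(left|right)$", "", scores$feature)
  df <- tibble(bundle = bundle, hemisphere = scores$hemisphere,
               z = scores$z)
  unknown <- setdiff(unique(bundle), layout$tract_order)
  if (length(unknown) > 0) {
    abort_fixelnorm(
      paste("tracts not in the spider layout:",
            paste(unknown, collapse = ", ")),
      "fixelnorm_layout_error")
  }
  # the midline CC is displayed on both hemisphere layers
  mid <- df$hemisphere == "midline"
  df <- dplyr::bind_rows(
    dplyr::mutate(df[!mid, ], layer = ifelse(.data$hemisphere == "L",
                                             "left", "right")),
    dplyr::mutate(df[mid, ], layer = "left"),
    dplyr::mutate(df[mid, ], layer = "right")
  )
  k <- length(layout$tract_order)
  df |>
    dplyr::mutate(
      axis = match(.data$bundle, layout$tract_order),
      angle = pi / 2 - (.data$axis - 1) * 2 * pi / k,
      clamped_low = !is.na(.data$z) & .data$z < layout$clamp_min,
      z_disp = pmin(pmax(.data$z, layout$clamp_min), 0),
      radius = (.data$z_disp - layout$clamp_min) / (0 - layout$clamp_min),
      x = .data$radius * cos(.data$angle),
      y = .data$radius * sin(.data$angle)
    ) |>
    dplyr::arrange(.data$layer, .data$axis)
}

.ring_df <- function(level, layout, n = 120) {
  r <- (max(level, layout$clamp_min) - layout$clamp_min) /
    (0 - layout$clamp_min)
  th <- seq(0, 2 * pi, length.out = n)
  tibble(x = r * cos(th), y = r * sin(th), level = level)
}

#' Spider plot of one patient's tract Z-scores
#'
#' Renders the radar display described by [spider_layout()]: two polygons
#' (left hemisphere blue on the lower layer, right hemisphere red on the
#' upper layer), grey guide rings, the dotted threshold ring, black data
#' points at or below the threshold, and bold labels for affected tracts.
#' Rendering is a pure function of the report and layout and never
#' mutates the report.
#'
#' @param report A [z_report()].
#' @param layout A [spider_layout()].
#' @param path Optional output stem; when given, `<path>.svg` and
#'   `<path>.png` are written.
#' @param annotate_li Annotate the laterality index under the title.
#' @return The ggplot object, invisibly when `path` is given.
#' @export
spider_plot <- function(report, layout = spider_layout(), path = NULL,
                        annotate_li = TRUE) {
  stopifnot(inherits(report, "z_report"), inherits(layout, "spider_layout"))
  df <- .spider_data(report, layout)
  rings <- dplyr::bind_rows(lapply(layout$rings, .ring_df,
                                   layout = layout))
  dotted <- .ring_df(layout$dotted_ring, layout)
  k <- length(layout$tract_order)
  spokes <- tibble(
    angle = pi / 2 - (seq_len(k) - 1) * 2 * pi / k,
    bundle = layout$tract_order
  ) |>
    dplyr::mutate(x = cos(.data$angle), y = sin(.data$angle))
  # bold a tract when either hemisphere is below the threshold
  affected <- df |>
    dplyr::group_by(.data$bundle) |>
    dplyr::summarise(bold = any(!is.na(.data$z) &
                                  .data$z < layout$bold_threshold),
                     .groups = "drop")
  labels <- dplyr::left_join(spokes, affected, by = "bundle") |>
    dplyr::mutate(bold = !is.na(.data$bold) & .data$bold,
                  lx = 1.15 * cos(.data$angle),
                  ly = 1.15 * sin(.data$angle))

  below <- dplyr::filter(df, !is.na(.data$z),
                         .data$z <= layout$dotted_ring)
  clamped <- dplyr::filter(df, .data$clamped_low)

  subtitle <- if (annotate_li && !is.na(report$li)) {
    sprintf("LI = %.4f", report$li)
  } else NULL

  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = rings,
                       ggplot2::aes(.data$x, .data$y,
                                    group = .data$level),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_path(data = dotted,
                       ggplot2::aes(.data$x, .data$y),
                       colour = "grey30", linetype = "dotted",
                       linewidth = 0.4) +
    ggplot2::geom_segment(data = spokes,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          colour = "grey85", linewidth = 0.25) +
    ggplot2::geom_polygon(data = dplyr::filter(df, .data$layer == "left"),
                          ggplot2::aes(.data$x, .data$y),
                          fill = layout$layer_colors[["left"]],
                          colour = layout$layer_colors[["left"]],
                          alpha = 0.25, linewidth = 0.6) +
    ggplot2::geom_polygon(data = dplyr::filter(df, .data$layer == "right"),
                          ggplot2::aes(.data$x, .data$y),
                          fill = layout$layer_colors[["right"]],
                          colour = layout$layer_colors[["right"]],
                          alpha = 0.25, linewidth = 0.6) +
    ggplot2::geom_point(data = df,
                        ggplot2::aes(.data$x, .data$y),
                        colour = "grey40", size = 0.9) +
    ggplot2::geom_point(data = below,
                        ggplot2::aes(.data$x, .data$y),
                        colour = "black", size = 1.4) +
    ggplot2::geom_point(data = clamped,
                        ggplot2::aes(.data$x, .data$y),
                        shape = 8, colour = "black", size = 2) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(.data$lx, .data$ly,
                                    label = .data$bundle,
                                    fontface = ifelse(.data$bold,
                                                      "bold", "plain")),
                       size = 3) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::labs(title = report$subject_id, subtitle = subtitle) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5),
                   plot.subtitle = ggplot2::element_text(hjust = 0.5))

  if (!is.null(path)) {
    grDevices::svg(paste0(path, ".svg"), width = 5, height = 5)
    print(p)
    grDevices::dev.off()
    grDevices::png(paste0(path, ".png"), width = 1000, height = 1000,
                   res = 200, type = "cairo")
    print(p)
    grDevices::dev.off()
    return(invisible(p))
  }
  p
}

#' @rdname spider_plot
#' @param object A [z_report()].
#' @param ... Passed to [spider_plot()].
#' @method autoplot z_report
#' @export
autoplot.z_report <- function(object, ...) {
  spider_plot(object, ...)
}

#' Multi-panel spider display for a patient cohort
#'
#' One spider panel per patient, shared layout, laterality index annotated
#' per panel, in deterministic (input) order.
#'
#' @param reports List of [z_report()] objects.
#' @param layout A [spider_layout()].
#' @param path Optional output stem for `<path>.svg` / `<path>.png`.
#' @param ncol Panel columns (default: near-square).
#' @return A patchwork object combining the panels.
#' @export
cohort_panel <- function(reports, layout = spider_layout(), path = NULL,
                         ncol = NULL) {
  if (length(reports) < 1) {
    abort_fixelnorm("need at least one report", "fixelnorm_parameter_error")
  }
  if (!requireNamespace("patchwork", quietly = TRUE)) {
    abort_fixelnorm("cohort_panel requires the patchwork package",
                    "fixelnorm_capability_error")
  }
  panels <- lapply(reports, spider_plot, layout = layout,
                   annotate_li = TRUE)
  if (is.null(ncol)) ncol <- ceiling(sqrt(length(panels)))
  p <- patchwork::wrap_plots(panels, ncol = ncol)
  if (!is.null(path)) {
    n_row <- ceiling(length(panels) / ncol)
    grDevices::svg(paste0(path, ".svg"), width = 4 * ncol, height = 4 * n_row)
    print(p)
    grDevices::dev.off()
    grDevices::png(paste0(path, ".png"), width = 800 * ncol,
                   height = 800 * n_row, res = 200, type = "cairo")
    print(p)
    grDevices::dev.off()
    return(invisible(p))
  }
  p
}
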