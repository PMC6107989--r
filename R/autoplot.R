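# ggplot2 view of a protein scene: same geometry as the SVG backend, drawn
# with geom_rect / geom_point / geom_text, for interactive use and for the
# PNG rasteriser.

#' Plot a protein scene with ggplot2
#'
#' Builds a ggplot from the scene's glyph layers: chain and feature
#' rectangles to scale in amino-acid units, phosphosite circles, and chain
#' labels in the left gutter. Legend entries come from the scene's category
#' -> fill map via an identity fill scale, so the rendered legend contains
#' exactly the scene's entries.
#'
#' @param object A `protein_scene`.
#' @param theme A `protein_theme`; default [default_theme()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' p <- draw_canvas(rela_fixture())
#' p <- draw_chains(p, rela_fixture(), label_size = 2.5)
#' p <- draw_domains(p, rela_fixture())
#' autoplot(p)
#' @export
autoplot.protein_scene <- function(object, theme = default_theme(), ...) {
  scene <- object
  canvas <- scene$canvas
  gg <- ggplot2::ggplot()
  for (layer in scene$layers) {
    d <- layer$data
    if (nrow(d) == 0L) next
    if (layer$kind == "rect") {
      gg <- gg + ggplot2::geom_rect(
        data = d,
        ggplot2::aes(xmin = .data$x_start, xmax = .data$x_end,
                     ymin = .data$y_center - .data$half_height,
                     ymax = .data$y_center + .data$half_height,
                     fill = .data$fill),
        colour = d$outline
      )
    } else if (layer$kind == "marker") {
      gg <- gg + ggplot2::geom_point(
        data = d,
        ggplot2::aes(x = .data$x, y = .data$y),
        size = d$size, fill = d$fill, shape = 21, colour = "black"
      )
    } else if (layer$kind == "label") {
      gg <- gg + ggplot2::geom_text(
        data = d,
        ggplot2::aes(x = .data$x, y = .data$y, label = .data$text),
        size = d$size, hjust = 1
      )
    }
  }
  gg <- gg + ggplot2::scale_fill_identity(
    guide = if (nrow(scene$legend) > 0L) "legend" else "none",
    breaks = scene$legend$fill,
    labels = scene$legend$category,
    name = theme$legend_title
  )
  gg <- gg + ggplot2::coord_cartesian(
    xlim = c(canvas$x_min, canvas$x_max),
    ylim = c(canvas$y_min, canvas$y_max),
    expand = FALSE
  )
  gg <- gg + ggplot2::labs(x = NULL, y = NULL,
                           title = scene$title, subtitle = scene$subtitle)
  base_theme <- if (theme$background == "grey") {
    ggplot2::theme_grey(base_size = theme$base_size)
  } else {
    ggplot2::theme_bw(base_size = theme$base_size)
  }
  gg <- gg + base_theme
  mods <- ggplot2::theme(legend.position = theme$legend_position)
  if (!theme$show_grid) {
    mods <- mods + ggplot2::theme(panel.grid.major = ggplot2::element_blank(),
                                  panel.grid.minor = ggplot2::element_blank(),
                                  panel.border = ggplot2::element_blank())
  }
  if (!theme$show_y_axis) {
    mods <- mods + ggplot2::theme(axis.text.y = ggplot2::element_blank())
  }
  if (!theme$show_ticks) {
    mods <- mods + ggplot2::theme(axis.ticks = ggplot2::element_blank())
  }
  gg + mods +
    ggplot2::scale_y_continuous(breaks = seq_len(canvas$n_bands))
}

#' @export
plot.protein_scene <- function(x, y, ...) {
  print(autoplot(x, ...))
  invisible(x)
}
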