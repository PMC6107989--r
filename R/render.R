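# Rendering: materialise a protein_scene as SVG or PNG under a theme.
#
# SVG is the primary backend: the scene geometry is serialised directly to
# SVG 1.1 elements (via xml2) in a fixed order with fixed number formatting,
# so two renders of the same scene and theme are byte-identical — a stable
# surface for snapshot tests and reproducible figures. PNG is rasterised
# from the same geometry through the ggplot view (cairo device).

#' Construct a rendering theme
#'
#' @param background `"grey"` (the familiar ggplot default panel) or
#'   `"white"`.
#' @param show_y_axis Show the stacking-band axis labels?
#' @param show_grid Show panel grid lines?
#' @param show_ticks Show x-axis tick marks (labels are always shown)?
#' @param base_size Base font size in points; glyph text scales from it.
#' @param legend_position `"right"`, `"top"` or `"none"`.
#' @param legend_title Legend title; empty string for none.
#' @return A `protein_theme` list.
#' @export
protein_theme <- function(background = c("grey", "white"),
                          show_y_axis = TRUE,
                          show_grid = TRUE,
                          show_ticks = TRUE,
                          base_size = 11,
                          legend_position = c("right", "top", "none"),
                          legend_title = "") {
  background <- match.arg(background)
  legend_position <- match.arg(legend_position)
  if (!is.numeric(base_size) || length(base_size) != 1L || base_size <= 0) {
    rlang::abort("`base_size` must be a single positive number.",
                 class = "protsketch_config_error")
  }
  structure(
    list(background = background,
         show_y_axis = isTRUE(show_y_axis),
         show_grid = isTRUE(show_grid),
         show_ticks = isTRUE(show_ticks),
         base_size = base_size,
         legend_position = legend_position,
         legend_title = as.character(legend_title)),
    class = "protein_theme"
  )
}

#' Default theme: grey panel, visible axes and grid
#' @param base_size Base font size in points.
#' @return A `protein_theme`.
#' @export
default_theme <- function(base_size = 11) {
  protein_theme(background = "grey", base_size = base_size)
}

#' Publication theme: white panel, no grid, no y axis or ticks
#'
#' Mirrors the common figure styling for protein schematics: white
#' background, grid and panel decorations removed, only the amino-acid
#' axis labels kept.
#'
#' @param base_size Base font size in points (default 10).
#' @param legend_position Legend placement.
#' @return A `protein_theme`.
#' @export
publication_theme <- function(base_size = 10, legend_position = "right") {
  protein_theme(background = "white", show_y_axis = FALSE, show_grid = FALSE,
                show_ticks = FALSE, base_size = base_size,
                legend_position = legend_position)
}

col2hex <- function(col) {
  out <- rep("none", length(col))
  ok <- !is.na(col)
  if (any(ok)) {
    m <- grDevices::col2rgb(col[ok])
    out[ok] <- grDevices::rgb(m[1, ], m[2, ], m[3, ], maxColorValue = 255)
  }
  out
}

num <- function(x) sprintf("%.2f", x)

# Scaling of glyph sizes: label/marker sizes are in mm (ggplot convention);
# 1 mm ~ 2.845 pt ~ 3.79 px at 96 dpi.
MM_TO_PX <- 3.7936

svg_text <- function(parent, x, y, text, size_px, anchor = "start",
                     weight = NULL, fill = "#000000") {
  node <- xml2::xml_add_child(
    parent, "text",
    x = num(x), y = num(y),
    `font-family` = "Helvetica, Arial, sans-serif",
    `font-size` = num(size_px),
    `text-anchor` = anchor,
    fill = fill
  )
  if (!is.null(weight)) xml2::xml_set_attr(node, "font-weight", weight)
  xml2::xml_text(node) <- text
  node
}

render_svg <- function(scene, theme, path, width) {
  canvas <- scene$canvas
  base <- theme$base_size
  grey_panel <- "#EBEBEB"

  subtitle_lines <- if (is.null(scene$subtitle)) character() else
    strsplit(scene$subtitle, "\n", fixed = TRUE)[[1]]
  legend <- scene$legend
  has_legend <- nrow(legend) > 0L && theme$legend_position != "none"

  mt <- 12
  if (!is.null(scene$title)) mt <- mt + base * 1.45 + 6
  if (length(subtitle_lines) > 0L) mt <- mt + length(subtitle_lines) * (base + 3) + 4
  if (has_legend && theme$legend_position == "top") {
    mt <- mt + base * 0.9 + 14
  }
  mb <- 10 + base * 0.9 + 10
  ml <- 8
  mr <- if (has_legend && theme$legend_position == "right") 160 else 8

  plot_h <- 70 * (canvas$y_max - canvas$y_min)
  height <- mt + plot_h + mb
  plot_w <- width - ml - mr

  sx <- function(x) ml + (x - canvas$x_min) / (canvas$x_max - canvas$x_min) * plot_w
  sy <- function(y) mt + (canvas$y_max - y) / (canvas$y_max - canvas$y_min) * plot_h

  root <- xml2::xml_new_root(
    "svg",
    xmlns = "http://www.w3.org/2000/svg",
    version = "1.1",
    width = num(width), height = num(height),
    viewBox = sprintf("0 0 %s %s", num(width), num(height))
  )
  xml2::xml_add_child(root, "rect", x = "0", y = "0",
                      width = num(width), height = num(height),
                      fill = "#FFFFFF")
  panel_fill <- if (theme$background == "grey") grey_panel else "#FFFFFF"
  xml2::xml_add_child(root, "rect", x = num(ml), y = num(mt),
                      width = num(plot_w), height = num(plot_h),
                      fill = panel_fill)

  ticks <- pretty(c(0, canvas$max_end))
  ticks <- ticks[ticks >= 0 & ticks <= canvas$x_max]
  if (theme$show_grid) {
    for (tk in ticks) {
      xml2::xml_add_child(root, "line",
                          x1 = num(sx(tk)), y1 = num(mt),
                          x2 = num(sx(tk)), y2 = num(mt + plot_h),
                          stroke = "#FFFFFF", `stroke-width` = "1")
    }
  }

  for (layer in scene$layers) {
    d <- layer$data
    if (nrow(d) == 0L) next
    if (layer$kind == "rect") {
      fills <- col2hex(d$fill)
      outlines <- col2hex(d$outline)
      for (i in seq_len(nrow(d))) {
        node <- xml2::xml_add_child(
          root, "rect",
          x = num(sx(d$x_start[i])),
          y = num(sy(d$y_center[i] + d$half_height[i])),
          width = num(sx(d$x_end[i]) - sx(d$x_start[i])),
          height = num(sy(d$y_center[i] - d$half_height[i]) -
                         sy(d$y_center[i] + d$half_height[i])),
          fill = fills[i]
        )
        if (outlines[i] != "none") {
          xml2::xml_set_attr(node, "stroke", outlines[i])
          xml2::xml_set_attr(node, "stroke-width", "1")
        }
      }
    } else if (layer$kind == "marker") {
      fills <- col2hex(d$fill)
      for (i in seq_len(nrow(d))) {
        xml2::xml_add_child(
          root, "circle",
          cx = num(sx(d$x[i])), cy = num(sy(d$y[i])),
          r = num(d$size[i] * MM_TO_PX / 2),
          fill = fills[i], stroke = "#000000", `stroke-width` = "0.7"
        )
      }
    } else if (layer$kind == "label") {
      for (i in seq_len(nrow(d))) {
        svg_text(root, sx(d$x[i]), sy(d$y[i]) + d$size[i] * MM_TO_PX * 0.35,
                 d$text[i], d$size[i] * MM_TO_PX, anchor = "end")
      }
    }
  }

  axis_y <- mt + plot_h
  for (tk in ticks) {
    if (theme$show_ticks) {
      xml2::xml_add_child(root, "line",
                          x1 = num(sx(tk)), y1 = num(axis_y),
                          x2 = num(sx(tk)), y2 = num(axis_y + 4),
                          stroke = "#333333", `stroke-width` = "1")
    }
    svg_text(root, sx(tk), axis_y + 8 + base * 0.9,
             format(tk, scientific = FALSE, trim = TRUE),
             base * 0.9, anchor = "middle", fill = "#4D4D4D")
  }
  if (theme$show_y_axis) {
    for (band in seq_len(canvas$n_bands)) {
      svg_text(root, ml + 2, sy(band) + base * 0.3,
               as.character(band), base * 0.9, fill = "#4D4D4D")
    }
  }

  cursor_y <- 12 + base * 1.45
  if (!is.null(scene$title)) {
    svg_text(root, ml + 2, cursor_y, scene$title, base * 1.45, weight = "bold")
    cursor_y <- cursor_y + 6
  }
  for (line in subtitle_lines) {
    cursor_y <- cursor_y + base + 3
    svg_text(root, ml + 2, cursor_y, line, base)
  }

  if (has_legend) {
    entry_px <- base * 0.9
    if (theme$legend_position == "right") {
      lx <- width - mr + 12
      ly <- mt + 8
      if (nzchar(theme$legend_title)) {
        svg_text(root, lx, ly + entry_px, theme$legend_title, entry_px,
                 weight = "bold")
        ly <- ly + entry_px + 8
      }
      for (i in seq_len(nrow(legend))) {
        yy <- ly + (i - 1) * (entry_px + 10)
        xml2::xml_add_child(root, "rect", x = num(lx), y = num(yy),
                            width = "12", height = "12",
                            fill = col2hex(legend$fill[i]))
        svg_text(root, lx + 17, yy + 10, legend$category[i], entry_px)
      }
    } else {
      lx <- ml + 2
      ly <- mt - 10
      if (nzchar(theme$legend_title)) {
        svg_text(root, lx, ly, theme$legend_title, entry_px, weight = "bold")
        lx <- lx + (nchar(theme$legend_title) + 2) * entry_px * 0.58
      }
      for (i in seq_len(nrow(legend))) {
        xml2::xml_add_child(root, "rect", x = num(lx), y = num(ly - 10),
                            width = "12", height = "12",
                            fill = col2hex(legend$fill[i]))
        lx <- lx + 17
        svg_text(root, lx, ly, legend$category[i], entry_px)
        lx <- lx + (nchar(legend$category[i]) + 2) * entry_px * 0.58
      }
    }
  }

  xml2::write_xml(root, path)
  invisible(path)
}

#' Render a protein scene to SVG or PNG
#'
#' SVG output serialises the scene geometry directly and is byte-stable:
#' rendering the same scene and theme twice yields identical files (no
#' timestamps or generated ids), and rectangle widths are proportional to
#' amino-acid spans under a single affine x transform. PNG output
#' rasterises the [autoplot()] view of the same scene through the cairo
#' device.
#'
#' @param scene A `protein_scene`.
#' @param theme A `protein_theme`; default [default_theme()].
#' @param out_path Output file path.
#' @param format `"svg"` or `"png"`; inferred from the extension of
#'   `out_path` when `NULL`.
#' @param width Image width in pixels.
#' @param dpi Raster resolution for PNG (default 300).
#' @return `out_path`, invisibly.
#' @examples
#' p <- draw_canvas(rela_fixture())
#' p <- draw_chains(p, rela_fixture(), label_size = 2.5)
#' p <- draw_domains(p, rela_fixture())
#' out <- file.path(tempdir(), "rela.svg")
#' render_scene(p, publication_theme(), out)
#' @export
render_scene <- function(scene, theme = default_theme(), out_path,
                         format = NULL, width = 760, dpi = 300) {
  if (!inherits(scene, "protein_scene")) {
    rlang::abort("`scene` must be a protein scene.",
                 class = "protsketch_validation_error")
  }
  if (!inherits(theme, "protein_theme")) {
    rlang::abort("`theme` must come from protein_theme() or a theme constructor.",
                 class = "protsketch_config_error")
  }
  if (is.null(format)) {
    format <- tolower(tools::file_ext(out_path))
  }
  if (!format %in% c("svg", "png")) {
    rlang::abort(sprintf("Unknown output format '%s' (use svg or png).", format),
                 class = "protsketch_config_error")
  }
  out_dir <- dirname(out_path)
  if (!dir.exists(out_dir) || file.access(out_dir, mode = 2) != 0) {
    rlang::abort(sprintf("Output directory '%s' is not writable.", out_dir),
                 class = "protsketch_io_error")
  }
  if (format == "svg") {
    render_svg(scene, theme, out_path, width = width)
  } else {
    height <- 70 * (scene$canvas$y_max - scene$canvas$y_min) + 120
    grDevices::png(out_path, width = width / 96 * dpi,
                   height = height / 96 * dpi, res = dpi, type = "cairo")
    on.exit(grDevices::dev.off(), add = TRUE)
    print(autoplot(scene, theme = theme))
  }
  invisible(out_path)
}
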