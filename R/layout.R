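# Layout: converts a feature table into renderer-independent geometry.
#
# A protein_scene holds a canvas (drawing extent in amino-acid x units and
# stacking-band y units), an ordered list of glyph layers, and legend
# entries. Later layers draw above earlier ones; the chain layer is always
# first. No drawing happens here — rendering backends (SVG writer, ggplot)
# consume the scene.

# Band geometry. The published figures fix none of these numerically; the
# values echo their look: chains are slimmer than the feature boxes drawn
# over them, and phosphosite markers sit on the upper chain edge.
CHAIN_HALF_HEIGHT <- 0.2
FEATURE_HALF_HEIGHT <- 0.25
PHOSPHO_Y_OFFSET <- 0.25
RIGHT_MARGIN_FRAC <- 0.10
LEFT_GUTTER_FRAC <- 0.20
Y_PAD <- 0.5

# Stable categorical palette (ColorBrewer-derived). Fills are assigned to
# the sorted distinct descriptions within each layer, so a given set of
# category names always maps to the same colors, across runs and machines.
CATEGORY_PALETTE <- c(
  "#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00", "#A65628",
  "#F781BF", "#66C2A5", "#FC8D62", "#8DA0CB", "#E78AC3", "#A6D854",
  "#FFD92F", "#B3B3B3"
)

category_fills <- function(descriptions) {
  cats <- sort(unique(descriptions))
  fills <- rep_len(CATEGORY_PALETTE, length(cats))
  stats::setNames(fills, cats)
}

new_scene <- function(canvas) {
  structure(
    list(
      canvas = canvas,
      layers = list(),
      legend = tibble::tibble(layer = character(), category = character(),
                              fill = character()),
      title = NULL,
      subtitle = NULL
    ),
    class = "protein_scene"
  )
}

add_layer <- function(scene, name, kind, data) {
  scene$layers[[length(scene$layers) + 1L]] <- list(name = name, kind = kind,
                                                    data = data)
  scene
}

has_layer <- function(scene, name) {
  any(purrr::map_chr(scene$layers, "name") == name)
}

require_chain_layer <- function(scene, caller) {
  if (!inherits(scene, "protein_scene")) {
    rlang::abort(sprintf("`%s()` needs a protein scene; start with draw_canvas().",
                         caller),
                 class = "protsketch_validation_error")
  }
  if (!has_layer(scene, "chains")) {
    rlang::abort(sprintf("`%s()` needs a chain layer; call draw_chains() first.",
                         caller),
                 class = "protsketch_validation_error")
  }
  invisible(scene)
}

#' Create the drawing canvas from a feature table
#'
#' The x extent is based on the length of the protein (the longest protein
#' when several are drawn), with a right margin and a left gutter reserved
#' for chain labels; the y extent is based on the number of proteins (one
#' stacking band per distinct `order` value, band 1 at the bottom).
#'
#' @param table A feature table with at least `end` and `order` columns.
#' @return A `protein_scene` with an empty layer list; pipe it into
#'   [draw_chains()] next.
#' @examples
#' p <- draw_canvas(rela_fixture())
#' p$canvas$x_max
#' @export
draw_canvas <- function(table) {
  if (is.null(table) || nrow(table) == 0L) {
    rlang::abort("`table` must contain at least one feature record.",
                 class = "protsketch_empty_error")
  }
  max_end <- max(table$end)
  k <- length(unique(table$order))
  canvas <- list(
    x_min = -LEFT_GUTTER_FRAC * max_end,
    x_max = (1 + RIGHT_MARGIN_FRAC) * max_end,
    y_min = 0.5 - Y_PAD,
    y_max = k + 0.5 + Y_PAD,
    max_end = max_end,
    n_bands = k
  )
  new_scene(canvas)
}

#' Draw the protein chains and their labels
#'
#' Adds one rectangle per CHAIN record, drawn to scale from `begin` to
#' `end` on the band given by the record's `order`, plus one text label per
#' chain in the left gutter. The default label is the UniProt entry name;
#' `labels` replaces them with custom names, one per CHAIN record in
#' bottom-up band order (entries annotated with processed forms carry
#' several chains on one band and therefore take several labels).
#'
#' @param scene A scene from [draw_canvas()].
#' @param table A feature table.
#' @param labels Optional character vector, one label per CHAIN record,
#'   bottom-up.
#' @param label_size Label text size (mm, as in ggplot2 text geoms).
#' @param fill,outline Chain fill and outline colors.
#' @return The scene with `chains` and `chain_labels` layers added.
#' @examples
#' p <- draw_canvas(rela_fixture())
#' p <- draw_chains(p, rela_fixture(), label_size = 2.5)
#' @export
draw_chains <- function(scene, table, labels = NULL, label_size = 4,
                        fill = "grey", outline = "black") {
  if (!inherits(scene, "protein_scene")) {
    rlang::abort("`scene` must come from draw_canvas().",
                 class = "protsketch_validation_error")
  }
  chains <- select_type(table, "CHAIN")
  if (nrow(chains) == 0L) {
    rlang::abort("`table` has no CHAIN records to draw.",
                 class = "protsketch_empty_error")
  }
  chains <- dplyr::arrange(chains, .data$order, .data$begin, .data$end)
  if (is.null(labels)) {
    labels <- chains$entryName
  } else {
    labels <- as.character(labels)
    if (length(labels) != nrow(chains)) {
      rlang::abort(
        sprintf("`labels` must have one entry per CHAIN record: expected %d, got %d.",
                nrow(chains), length(labels)),
        class = "protsketch_config_error"
      )
    }
  }
  rects <- tibble::tibble(
    x_start = chains$begin,
    x_end = chains$end,
    y_center = as.numeric(chains$order),
    half_height = CHAIN_HALF_HEIGHT,
    fill = fill,
    outline = outline,
    category = NA_character_
  )
  label_glyphs <- tibble::tibble(
    x = -0.02 * scene$canvas$max_end,
    y = as.numeric(chains$order),
    text = labels,
    size = label_size
  )
  scene <- add_layer(scene, "chains", "rect", rects)
  add_layer(scene, "chain_labels", "label", label_glyphs)
}

# Shared implementation for the to-scale feature-box layers. Each layer is
# colored per distinct description with one legend entry per category;
# records falling outside their protein's chain extent are reported (never
# silently clipped).
draw_feature_layer <- function(scene, table, feature_type, layer_name, caller) {
  require_chain_layer(scene, caller)
  sub <- select_type(table, feature_type)
  if (nrow(sub) == 0L) {
    return(add_layer(scene, layer_name, "rect",
                     tibble::tibble(x_start = numeric(), x_end = numeric(),
                                    y_center = numeric(), half_height = numeric(),
                                    fill = character(), outline = character(),
                                    category = character())))
  }
  check_containment(scene, sub)
  fills <- category_fills(sub$description)
  rects <- tibble::tibble(
    x_start = sub$begin,
    x_end = sub$end,
    y_center = as.numeric(sub$order),
    half_height = FEATURE_HALF_HEIGHT,
    fill = unname(fills[sub$description]),
    outline = NA_character_,
    category = sub$description
  )
  scene <- add_layer(scene, layer_name, "rect", rects)
  scene$legend <- dplyr::bind_rows(
    scene$legend,
    tibble::tibble(layer = layer_name, category = names(fills),
                   fill = unname(fills))
  )
  scene
}

check_containment <- function(scene, sub) {
  chains <- NULL
  for (layer in scene$layers) {
    if (layer$name == "chains") chains <- layer$data
  }
  extents <- dplyr::summarise(
    dplyr::group_by(chains, .data$y_center),
    x_lo = min(.data$x_start), x_hi = max(.data$x_end), .groups = "drop"
  )
  joined <- dplyr::left_join(
    tibble::tibble(y_center = as.numeric(sub$order), begin = sub$begin,
                   end = sub$end, description = sub$description),
    extents, by = "y_center"
  )
  outside <- joined[!is.na(joined$x_lo) &
                      (joined$begin < joined$x_lo | joined$end > joined$x_hi), ]
  if (nrow(outside) > 0L) {
    rlang::warn(
      sprintf("%d feature(s) extend beyond their chain: %s",
              nrow(outside),
              paste(utils::head(outside$description, 3), collapse = "; "))
    )
  }
  invisible(NULL)
}

#' Add protein domains to a scene
#'
#' Draws one to-scale rectangle per DOMAIN record, slightly taller than the
#' chain band, colored per distinct description with a legend entry. Custom
#' domains can be drawn by passing any data frame carrying the canonical
#' columns.
#'
#' @inheritParams draw_chains
#' @return The scene with a `domains` layer added (a no-op layer when the
#'   table has no DOMAIN records).
#' @examples
#' p <- draw_canvas(rela_fixture())
#' p <- draw_chains(p, rela_fixture())
#' p <- draw_domains(p, rela_fixture())
#' @export
draw_domains <- function(scene, table) {
  draw_feature_layer(scene, table, "DOMAIN", "domains", "draw_domains")
}

#' Add annotated regions to a scene
#' @inheritParams draw_domains
#' @return The scene with a `regions` layer added.
#' @export
draw_regions <- function(scene, table) {
  draw_feature_layer(scene, table, "REGION", "regions", "draw_regions")
}

#' Add sequence motifs to a scene
#' @inheritParams draw_domains
#' @return The scene with a `motifs` layer added.
#' @export
draw_motif <- function(scene, table) {
  draw_feature_layer(scene, table, "MOTIF", "motifs", "draw_motif")
}

#' Add repeat elements to a scene
#' @inheritParams draw_domains
#' @return The scene with a `repeats` layer added.
#' @export
draw_repeat <- function(scene, table) {
  draw_feature_layer(scene, table, "REPEAT", "repeats", "draw_repeat")
}

#' Add phosphorylation-site markers to a scene
#'
#' Places one circle per phosphosite (selected with [select_phospho()]) at
#' the site's position, just above the chain's upper edge. Yellow circles
#' are the conventional default; size and fill are overridable.
#'
#' @inheritParams draw_chains
#' @param size Marker size (mm, as in ggplot2 point geoms).
#' @param fill Marker fill color.
#' @return The scene with a `phospho` layer of circle markers added.
#' @examples
#' p <- draw_canvas(rela_fixture())
#' p <- draw_chains(p, rela_fixture())
#' p <- draw_phospho(p, rela_fixture(), size = 3)
#' @export
draw_phospho <- function(scene, table, size = 2, fill = "yellow") {
  require_chain_layer(scene, "draw_phospho")
  sites <- select_phospho(table)
  markers <- tibble::tibble(
    x = (sites$begin + sites$end) / 2,
    y = as.numeric(sites$order) + PHOSPHO_Y_OFFSET,
    size = rep(size, nrow(sites)),
    fill = rep(fill, nrow(sites)),
    shape = rep("circle", nrow(sites))
  )
  add_layer(scene, "phospho", "marker", markers)
}

#' Add a title and optional subtitle to a scene
#'
#' @param scene A protein scene.
#' @param title Title string.
#' @param subtitle Optional subtitle; embedded newlines make multiple lines.
#' @return The scene with titles set.
#' @export
add_title <- function(scene, title, subtitle = NULL) {
  if (!inherits(scene, "protein_scene")) {
    rlang::abort("`scene` must be a protein scene.",
                 class = "protsketch_validation_error")
  }
  scene$title <- title
  scene$subtitle <- subtitle
  scene
}

#' @export
print.protein_scene <- function(x, ...) {
  cat(sprintf("# Protein scene: %d band(s), x in [%.1f, %.1f]\n",
              x$canvas$n_bands, x$canvas$x_min, x$canvas$x_max))
  for (layer in x$layers) {
    cat(sprintf("  layer %-12s (%s): %d glyph(s)\n",
                layer$name, layer$kind, nrow(layer$data)))
  }
  if (nrow(x$legend) > 0L) {
    cat(sprintf("  legend: %s\n", paste(x$legend$category, collapse = ", ")))
  }
  invisible(x)
}

#' Tidy a protein scene into one row per glyph
#'
#' Broom-style accessor: flattens all layers into a single tibble with the
#' layer name, glyph kind and geometry columns, convenient for inspection
#' and testing.
#'
#' @param x A `protein_scene`.
#' @param ... Unused.
#' @return A tibble with columns `layer`, `kind`, and the glyph fields.
#' @export
tidy.protein_scene <- function(x, ...) {
  purrr::map_dfr(x$layers, function(ly) {
    if (nrow(ly$data) == 0L) {
      return(tibble::tibble())
    }
    dplyr::bind_cols(
      tibble::tibble(layer = ly$name, kind = ly$kind),
      ly$data
    )
  })
}

#' One-row summary of a protein scene
#'
#' @param x A `protein_scene`.
#' @param ... Unused.
#' @return A one-row tibble: band count, layer count, glyph count, legend
#'   entry count, and x extent.
#' @export
glance.protein_scene <- function(x, ...) {
  tibble::tibble(
    n_bands = x$canvas$n_bands,
    n_layers = length(x$layers),
    n_glyphs = sum(purrr::map_int(x$layers, ~ nrow(.x$data))),
    n_legend = nrow(x$legend),
    x_min = x$canvas$x_min,
    x_max = x$canvas$x_max
  )
}

#' Serialise a scene to JSON
#'
#' A renderer-independent dump of the canvas, layers and legend, intended
#' for debugging and snapshot testing. Deterministic for identical scenes.
#'
#' @param scene A `protein_scene`.
#' @return A JSON string.
#' @export
scene_to_json <- function(scene) {
  payload <- list(
    canvas = scene$canvas,
    layers = purrr::map(scene$layers, function(layer) {
      list(name = layer$name, kind = layer$kind,
           data = as.data.frame(layer$data))
    }),
    legend = as.data.frame(scene$legend),
    title = scene$title,
    subtitle = scene$subtitle
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
}
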