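# Deterministic SVG renderings of the four map idioms: component planes
# (grey ramp, dark = high), area label maps (region colours), star-glyph
# property planes, and blue-to-red weight fields. All output is a pure
# function of its inputs (fixed number formatting, no timestamps), so
# re-rendering identical objects yields byte-identical files.

REGION_COLOURS <- c(Catalonia = "#000000", Biscay = "#0000CC",
                    Gipuzkoa = "#CC0000")
FALLBACK_COLOURS <- c("#007700", "#AA6600", "#7700AA", "#006666")

fmt <- function(x) sprintf("%.3f", x)

region_colour <- function(regions) {
  u <- unique(regions)
  extra <- setdiff(u, names(REGION_COLOURS))
  pal <- c(REGION_COLOURS,
           stats::setNames(rep_len(FALLBACK_COLOURS, length(extra)), extra))
  unname(pal[regions])
}

grey_ramp <- function(v) {
  # dark grey = high value
  g <- round(235 * (1 - v))
  sprintf("#%02X%02X%02X", g, g, g)
}

blue_red_ramp <- function(v) {
  r <- round(255 * v)
  sprintf("#%02X%02X%02X", r, 0L, 255L - r)
}

hex_points <- function(cx, cy, cell) {
  R <- cell / sqrt(3)
  ang <- (c(90, 150, 210, 270, 330, 30)) * pi / 180
  paste(fmt(cx + R * cos(ang)), fmt(cy - R * sin(ang)),
        sep = ",", collapse = " ")
}

svg_open <- function(width, height) {
  c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" ',
                   'height="%s" viewBox="0 0 %s %s">'),
            fmt(width), fmt(height), fmt(width), fmt(height)),
    '<rect width="100%" height="100%" fill="#FFFFFF"/>')
}

svg_text <- function(x, y, s, size, fill = "#000000", anchor = "middle") {
  sprintf(paste0('<text x="%s" y="%s" font-size="%s" font-family="sans-serif" ',
                 'text-anchor="%s" fill="%s">%s</text>'),
          fmt(x), fmt(y), fmt(size), anchor, fill, s)
}

# one hex panel: returns svg fragment lines for the grid with given fills
hex_panel <- function(grid, fills, ox, oy, cell, strokes = NULL,
                      stroke_width = NULL, index_labels = TRUE) {
  cx <- ox + grid$pos[, 1L] * cell
  cy <- oy + grid$pos[, 2L] * cell
  if (is.null(strokes)) strokes <- rep("#999999", grid$n_units)
  if (is.null(stroke_width)) stroke_width <- rep(0.5, grid$n_units)
  lines <- vapply(seq_len(grid$n_units), function(i) {
    sprintf('<polygon points="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
            hex_points(cx[i], cy[i], cell), fills[i], strokes[i],
            fmt(stroke_width[i]))
  }, "")
  if (index_labels) {
    lines <- c(lines, vapply(seq_len(grid$n_units), function(i) {
      svg_text(cx[i], cy[i] + cell * 0.42, i, cell * 0.16, fill = "#888888")
    }, ""))
  }
  list(lines = lines, cx = cx, cy = cy)
}

panel_extent <- function(grid, cell) {
  c(w = (max(grid$pos[, 1L]) + 1.2) * cell,
    h = (max(grid$pos[, 2L]) + 1.4) * cell)
}

#' Render component planes as SVG
#'
#' One hexagonal panel per indicator, all sharing the neuron layout of the
#' SOM; each neuron is filled on a grey ramp where darker grey means a
#' higher indicator value (each plane is scaled over its own value range;
#' a constant plane renders in a uniform mid grey). Neuron indices are
#' embedded so planes align visually with the other map renderings.
#'
#' @param som a [train_som()] result.
#' @param codes indicator codes to render (default all).
#' @param path output SVG path.
#' @param cell hexagon cell size in pixels.
#' @param ncol panels per row.
#' @return `path`, invisibly.
#' @export
plot_component_planes <- function(som, codes = colnames(som$codebook), path,
                                  cell = 26, ncol = 3L) {
  stopifnot(inherits(som, "trained_som"))
  bad <- setdiff(codes, colnames(som$codebook))
  if (length(bad)) stop("unknown code(s): ", paste(bad, collapse = ", "))
  ext <- panel_extent(som$grid, cell)
  pw <- ext[["w"]] + 10
  ph <- ext[["h"]] + 24
  ncol <- min(ncol, length(codes))
  nrow <- ceiling(length(codes) / ncol)
  out <- svg_open(ncol * pw + 10, nrow * ph + 10)
  for (k in seq_along(codes)) {
    plane <- component_plane(som, codes[k])
    rng <- range(plane)
    v <- if (diff(rng) > 0) (plane - rng[1L]) / diff(rng) else {
      rep(0.5, length(plane))
    }
    px <- ((k - 1L) %% ncol) * pw + 10
    py <- ((k - 1L) %/% ncol) * ph + 24
    out <- c(out, svg_text(px + ext[["w"]] / 2, py - 8, codes[k], 12))
    out <- c(out, hex_panel(som$grid, grey_ramp(v), px + cell / 2,
                            py + cell / 2, cell)$lines)
  }
  out <- c(out, "</svg>")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Render the area label map as SVG
#'
#' Area labels are drawn at their BMU neuron; labels sharing a neuron are
#' stacked in alphabetical order. Labels are coloured by region (black for
#' Catalonia, blue for Biscay, red for Gipuzkoa; other regions get a
#' fallback palette).
#'
#' @param som a [train_som()] result.
#' @param path output SVG path.
#' @param cell hexagon cell size in pixels.
#' @return `path`, invisibly.
#' @export
plot_label_map <- function(som, path, cell = 34) {
  stopifnot(inherits(som, "trained_som"))
  ext <- panel_extent(som$grid, cell)
  out <- svg_open(ext[["w"]] + 20, ext[["h"]] + 30)
  panel <- hex_panel(som$grid, rep("#F4F4F4", som$grid$n_units),
                     10 + cell / 2, 20 + cell / 2, cell)
  out <- c(out, panel$lines)
  regions <- stats::setNames(som$meta$areas$region, som$meta$areas$label)
  for (n in sort(unique(som$assignments))) {
    labs <- sort(names(som$assignments)[som$assignments == n])
    for (i in seq_along(labs)) {
      out <- c(out, svg_text(
        panel$cx[n],
        panel$cy[n] - cell * 0.22 + (i - 1L) * cell * 0.22,
        labs[i], cell * 0.2,
        fill = region_colour(regions[[labs[i]]])))
    }
  }
  out <- c(out, "</svg>")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Render the star-glyph property plane as SVG
#'
#' One glyph per neuron: branch k points clockwise from vertical at angle
#' 2*pi*k/d, with radius proportional to the neuron's normalized codebook
#' value for indicator k; branch tips are connected into a closed shape.
#' A legend lists the indicator order clockwise. More than 36 indicators
#' triggers a legibility warning.
#'
#' @param som a [train_som()] result.
#' @param path output SVG path.
#' @param cell hexagon cell size in pixels.
#' @return `path`, invisibly.
#' @export
plot_star_glyphs <- function(som, path, cell = 34) {
  stopifnot(inherits(som, "trained_som"))
  d <- ncol(som$codebook)
  if (d > 36L) warning(d, " indicators: star glyphs will be illegible")
  ext <- panel_extent(som$grid, cell)
  legend_h <- 16 * ceiling(d / 8) + 10
  out <- svg_open(ext[["w"]] + 20, ext[["h"]] + 30 + legend_h)
  panel <- hex_panel(som$grid, rep("#FFFFFF", som$grid$n_units),
                     10 + cell / 2, 20 + cell / 2, cell)
  out <- c(out, panel$lines)
  theta <- 2 * pi * (seq_len(d) - 1L) / d   # clockwise from vertical
  dx <- sin(theta); dy <- -cos(theta)
  rmax <- cell * 0.42
  vals <- pmin(pmax(som$codebook, 0), 1)
  for (n in seq_len(som$grid$n_units)) {
    r <- (0.1 + 0.9 * vals[n, ]) * rmax
    pts <- paste(fmt(panel$cx[n] + r * dx), fmt(panel$cy[n] + r * dy),
                 sep = ",", collapse = " ")
    out <- c(out, sprintf(
      '<polygon points="%s" fill="#BBBBDD" fill-opacity="0.7" stroke="#333366" stroke-width="0.8"/>',
      pts))
  }
  ly <- 20 + ext[["h"]] + 14
  legend <- paste0(seq_len(d), ":", colnames(som$codebook))
  for (i in seq_along(legend)) {
    out <- c(out, svg_text(14 + ((i - 1L) %% 8L) * (ext[["w"]] / 8),
                           ly + ((i - 1L) %/% 8L) * 16, legend[i], 10,
                           anchor = "start"))
  }
  out <- c(out, svg_text(10, ly + legend_h - 12,
                         "indicator order clockwise from vertical", 9,
                         fill = "#555555", anchor = "start"))
  out <- c(out, "</svg>")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Render a weight field as SVG
#'
#' Neurons are filled on a blue-to-red ramp (red = high weight); if the
#' field carries a selected-region mask, the masked neurons are outlined.
#'
#' @param field a [propagate()] / [select_region()] result.
#' @param som the [train_som()] of the field's target map (provides the
#'   grid layout).
#' @param path output SVG path.
#' @param cell hexagon cell size in pixels.
#' @return `path`, invisibly.
#' @export
plot_weight_field <- function(field, som, path, cell = 26) {
  stopifnot(inherits(field, "weight_field"), inherits(som, "trained_som"))
  if (length(field$weights) != som$grid$n_units) {
    stop("field has ", length(field$weights), " weights but the grid has ",
         som$grid$n_units, " neurons")
  }
  ext <- panel_extent(som$grid, cell)
  out <- svg_open(ext[["w"]] + 20, ext[["h"]] + 30)
  strokes <- rep("#999999", som$grid$n_units)
  widths <- rep(0.5, som$grid$n_units)
  if (!is.null(field$mask)) {
    strokes[field$mask] <- "#000000"
    widths[field$mask] <- 2
  }
  out <- c(out, svg_text(10 + ext[["w"]] / 2, 14,
                         sprintf("%s weights on the %s-SOM",
                                 field$direction, field$target_dataset), 11))
  out <- c(out, hex_panel(som$grid, blue_red_ramp(field$weights),
                          10 + cell / 2, 20 + cell / 2, cell,
                          strokes = strokes, stroke_width = widths)$lines)
  out <- c(out, "</svg>")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
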