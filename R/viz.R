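# Figure conventions, rendered as SVG.
#
# Contour styling follows the standard presentation for these maps:
# isoeccentricity contours are solid and thicker, with an extra-thick
# contour every 10 deg, shaded red (central) -> blue -> green (peripheral);
# isopolar angle contours are thinner, dashed in the upper field, dotted in
# the lower field, with the horizontal meridian as a thick dashed line,
# shaded green (lower) -> blue (horizontal meridian) -> red (upper).

#' Contour style
#'
#' @param quantity `"eccentricity"` or `"polar_angle"`.
#' @param interval contour interval, deg, `> 0`.
#' @param emphasis_interval heavier contour every this many deg; must be an
#'   integer multiple of `interval`. Defaults: 10 for eccentricity
#'   (extra-thick solid), 20 for polar angle (slightly thicker).
#' @param palette vector of colors anchoring the shading ramp, low to high.
#' @return list of class `contour_style`.
#' @export
contour_style <- function(quantity = c("eccentricity", "polar_angle"),
                          interval = if (quantity == "eccentricity") 2 else 5,
                          emphasis_interval = NULL, palette = NULL) {
  quantity <- match.arg(quantity)
  if (is.null(emphasis_interval))
    emphasis_interval <- if (quantity == "eccentricity") 10 else 20
  stopifnot(interval > 0)
  if (abs(emphasis_interval / interval -
          round(emphasis_interval / interval)) > 1e-9)
    stop("emphasis interval must be an integer multiple of the interval")
  if (is.null(palette)) {
    palette <- if (quantity == "eccentricity")
      c("#cc2222", "#2244cc", "#22aa44")   # central -> middle -> peripheral
    else
      c("#22aa44", "#2244cc", "#cc2222")   # lower -> HM -> upper
  }
  structure(list(quantity = quantity, interval = interval,
                 emphasis_interval = emphasis_interval, palette = palette),
            class = "contour_style")
}

# palette for field sign shade: mirror (-1) yellow, indeterminate gray,
# nonmirror (+1) blue-purple
sign_shade_color <- function(shade) {
  ramp <- grDevices::colorRamp(c("#e6c820", "#808080", "#5a3cc8"),
                               space = "Lab")
  rgb <- ramp((shade + 1) / 2)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

# ---- minimal deterministic SVG emitter --------------------------------------

svg_num <- function(x) sprintf("%.3f", x)

svg_header <- function(width, height) {
  sprintf(paste0(
    "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%s\" height=\"%s\" ",
    "viewBox=\"0 0 %s %s\">"),
    svg_num(width), svg_num(height), svg_num(width), svg_num(height))
}

svg_polyline <- function(xy, stroke, width, dash = NULL, opacity = 1) {
  pts <- paste(sprintf("%s,%s", svg_num(xy[, 1]), svg_num(xy[, 2])),
               collapse = " ")
  dash_attr <- if (!is.null(dash))
    sprintf(" stroke-dasharray=\"%s\"", dash) else ""
  sprintf(paste0("<polyline points=\"%s\" fill=\"none\" stroke=\"%s\" ",
                 "stroke-width=\"%s\"%s stroke-opacity=\"%s\"/>"),
          pts, stroke, svg_num(width), dash_attr, svg_num(opacity))
}

svg_rect <- function(x, y, w, h, fill, opacity = 1) {
  sprintf(paste0("<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" ",
                 "fill=\"%s\" fill-opacity=\"%s\"/>"),
          svg_num(x), svg_num(y), svg_num(w), svg_num(h), fill,
          svg_num(opacity))
}

svg_line <- function(x1, y1, x2, y2, stroke, width) {
  sprintf(paste0("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
                 "stroke=\"%s\" stroke-width=\"%s\"/>"),
          svg_num(x1), svg_num(y1), svg_num(x2), svg_num(y2), stroke,
          svg_num(width))
}

svg_polygon <- function(xy, fill) {
  pts <- paste(sprintf("%s,%s", svg_num(xy[, 1]), svg_num(xy[, 2])),
               collapse = " ")
  sprintf("<polygon points=\"%s\" fill=\"%s\"/>", pts, fill)
}

# world (mm, y up) -> page (px, y down) mapping for a grid geometry
svg_frame <- function(geometry, scale = 40, margin = 10) {
  g <- geometry
  xr <- c(g$origin[1] - g$spacing / 2,
          g$origin[1] + (g$nx - 0.5) * g$spacing)
  yr <- c(g$origin[2] - g$spacing / 2,
          g$origin[2] + (g$ny - 0.5) * g$spacing)
  list(tx = function(x) (x - xr[1]) * scale + margin,
       ty = function(y) (yr[2] - y) * scale + margin,
       width = diff(xr) * scale + 2 * margin,
       height = diff(yr) * scale + 2 * margin,
       scale = scale)
}

finish_svg <- function(frame, elements, file) {
  doc <- c(svg_header(frame$width, frame$height), elements, "</svg>")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(file))
  }
  paste(doc, collapse = "\n")
}

# ---- drawings ---------------------------------------------------------------

# contour elements shared by contour_map and sign_overlay
contour_elements <- function(field, style, frame) {
  rng <- range(field$values, na.rm = TRUE)
  lo <- ceiling(rng[1] / style$interval) * style$interval
  hi <- floor(rng[2] / style$interval) * style$interval
  if (lo > hi || diff(rng) == 0) return(character(0))
  levels <- seq(lo, hi, by = style$interval)
  levels <- levels[levels >= rng[1] & levels <= rng[2]]
  if (length(levels) == 0) return(character(0))
  ax <- grid_axes(field)
  z <- field$values
  zfill <- z
  zfill[is.na(zfill)] <- mean(z, na.rm = TRUE)
  elements <- character(0)
  ramp <- grDevices::colorRamp(style$palette, space = "Lab")
  for (lev in levels) {
    cl <- grDevices::contourLines(ax$x, ax$y, zfill, levels = lev)
    if (length(cl) == 0) next
    frac <- if (diff(rng) > 0) (lev - rng[1]) / diff(rng) else 0.5
    col <- ramp(frac)
    col <- grDevices::rgb(col[1], col[2], col[3], maxColorValue = 255)
    emphasized <- abs(lev / style$emphasis_interval -
                        round(lev / style$emphasis_interval)) < 1e-9
    if (style$quantity == "eccentricity") {
      lw <- if (emphasized) 2.4 else 1.1
      dash <- NULL
    } else {
      if (abs(lev) < 1e-9) {           # horizontal meridian: thick dashed
        lw <- 2.2; dash <- "8,4"
      } else if (lev > 0) {            # upper field: dashed
        lw <- if (emphasized) 1.2 else 0.7; dash <- "6,3"
      } else {                         # lower field: dotted
        lw <- if (emphasized) 1.2 else 0.7; dash <- "1.5,3"
      }
    }
    for (piece in cl) {
      xy <- clip_to_support(cbind(piece$x, piece$y), field)
      for (part in xy) {
        if (nrow(part) < 2) next
        page <- cbind(frame$tx(part[, 1]), frame$ty(part[, 2]))
        elements <- c(elements, svg_polyline(page, col, lw, dash))
      }
    }
  }
  elements
}

# split a contour polyline into runs whose vertices lie on supported cells
clip_to_support <- function(xy, field) {
  g <- field$geometry
  ix <- pmin(g$nx, pmax(1, round((xy[, 1] - g$origin[1]) / g$spacing) + 1))
  iy <- pmin(g$ny, pmax(1, round((xy[, 2] - g$origin[2]) / g$spacing) + 1))
  ok <- field$support[cbind(ix, iy)]
  if (all(ok)) return(list(xy))
  runs <- rle(ok)
  stops <- cumsum(runs$lengths)
  starts <- c(1, utils::head(stops, -1) + 1)
  lapply(which(runs$values), function(k) {
    xy[starts[k]:stops[k], , drop = FALSE]
  })
}

#' Contour map of a gridded field
#'
#' Draws contour lines at every multiple of the style's interval within the
#' data range, with the line textures and color ramps described in
#' [contour_style()]. Output is deterministic for fixed input.
#'
#' @param field a `grid_field`.
#' @param style a [contour_style()]; defaults to the style matching the
#'   field's quantity tag.
#' @param file output path; if `NULL`, the SVG text is returned.
#' @param scale px per mm.
#' @return `invisible(file)`, or the SVG document as a character scalar.
#' @export
contour_map <- function(field, style = NULL, file = NULL, scale = 40) {
  stopifnot(inherits(field, "grid_field"))
  if (is.null(style)) {
    style <- contour_style(if (field$quantity == "polar_angle")
      "polar_angle" else "eccentricity")
  }
  if (!any(field$support)) {
    warning("field is unsupported everywhere; empty drawing")
    frame <- svg_frame(field$geometry, scale)
    return(finish_svg(frame, character(0), file))
  }
  frame <- svg_frame(field$geometry, scale)
  finish_svg(frame, contour_elements(field, style, frame), file)
}

#' Arrow diagram of raw receptive field data
#'
#' One arrow per record, centered at the cortical recording site: arrow
#' length is proportional to the eccentricity of the receptive field center
#' and arrow angle is the polar angle mapped per the left-hemifield
#' convention (horizontal meridian points left; upper field rotates
#' clockwise toward up). Upper-field arrows are drawn bold. A record with
#' `r = 0` becomes a dot.
#'
#' @param table a normalized [rf_table()].
#' @param scale_arrow mm of cortex per deg of eccentricity; default 0.02.
#' @param file output path; if `NULL` the SVG text is returned.
#' @param scale px per mm.
#' @return `invisible(file)` or the SVG document.
#' @export
arrow_diagram <- function(table, scale_arrow = 0.02, file = NULL,
                          scale = 40) {
  stopifnot(inherits(table, "rf_table"))
  pad <- 1
  g <- grid_geometry(c(min(c(table$x, 0)) - pad, min(c(table$y, 0)) - pad), 1,
                     max(2, ceiling(diff(range(table$x)) + 2 * pad)),
                     max(2, ceiling(diff(range(table$y)) + 2 * pad)))
  frame <- svg_frame(g, scale)
  elements <- character(0)
  for (i in seq_len(nrow(table))) {
    len <- table$r[i] * scale_arrow
    th <- table$theta[i] * pi / 180
    dir <- c(-cos(th), sin(th))        # left hemifield convention
    bold <- table$theta[i] > 0
    cx <- table$x[i]; cy <- table$y[i]
    if (len == 0) {
      elements <- c(elements, svg_rect(frame$tx(cx) - 0.8,
                                       frame$ty(cy) - 0.8,
                                       1.6, 1.6, "#000000"))
      next
    }
    a <- c(cx, cy) - dir * len / 2
    b <- c(cx, cy) + dir * len / 2
    lw <- if (bold) 1.8 else 0.8
    elements <- c(elements,
                  svg_line(frame$tx(a[1]), frame$ty(a[2]),
                           frame$tx(b[1]), frame$ty(b[2]), "#000000", lw))
    # arrowhead at b
    hd <- 0.08 * frame$scale / 40 + len * 0.15
    perp <- c(-dir[2], dir[1])
    tri <- rbind(b,
                 b - dir * hd + perp * hd * 0.5,
                 b - dir * hd - perp * hd * 0.5)
    page <- cbind(frame$tx(tri[, 1]), frame$ty(tri[, 2]))
    elements <- c(elements, svg_polygon(page, "#000000"))
  }
  finish_svg(frame, elements, file)
}

#' Field sign overlay
#'
#' Composites, in order: an optional background image, the sigmoidally
#' shaded field sign layer at partial opacity (mirror yellow, nonmirror
#' blue-purple, indeterminate gray), contour drawings, and border
#' polylines.
#'
#' @param map a classified `field_sign_map`.
#' @param contours list of `grid_field`/[contour_style()] pairs to overlay,
#'   e.g. `list(list(field = ecc), list(field = pol))`; styles default by
#'   quantity.
#' @param borders optional list of polyline matrices (mm) drawn as medium
#'   gray lines (e.g. recovered or true sign borders).
#' @param background optional path to a raster image placed underneath.
#' @param opacity shade layer opacity; default 0.75.
#' @param file output path; if `NULL` the SVG text is returned.
#' @param scale px per mm.
#' @return `invisible(file)` or the SVG document.
#' @export
sign_overlay <- function(map, contours = list(), borders = NULL,
                         background = NULL, opacity = 0.75, file = NULL,
                         scale = 40) {
  stopifnot(inherits(map, "field_sign_map"), !is.null(map$shade))
  g <- map$geometry
  frame <- svg_frame(g, scale)
  elements <- character(0)
  if (!is.null(background)) {
    elements <- c(elements, sprintf(
      "<image href=\"%s\" x=\"0\" y=\"0\" width=\"%s\" height=\"%s\"/>",
      background, svg_num(frame$width), svg_num(frame$height)))
  }
  ax <- grid_axes(map)
  h <- g$spacing
  for (iy in seq_len(g$ny)) {
    # merge runs of equal color along x to keep files small
    shade_row <- map$shade[, iy]
    cols <- ifelse(is.na(shade_row), NA_character_,
                   sign_shade_color(ifelse(is.na(shade_row), 0, shade_row)))
    ix <- 1L
    while (ix <= g$nx) {
      if (is.na(cols[ix])) { ix <- ix + 1L; next }
      jx <- ix
      while (jx < g$nx && !is.na(cols[jx + 1L]) &&
             cols[jx + 1L] == cols[ix]) jx <- jx + 1L
      elements <- c(elements, svg_rect(
        frame$tx(ax$x[ix] - h / 2), frame$ty(ax$y[iy] + h / 2),
        (jx - ix + 1) * h * frame$scale, h * frame$scale,
        cols[ix], opacity))
      ix <- jx + 1L
    }
  }
  for (ct in contours) {
    field <- ct$field
    style <- if (!is.null(ct$style)) ct$style else
      contour_style(if (field$quantity == "polar_angle") "polar_angle"
                    else "eccentricity")
    if (!same_geometry(field$geometry, g))
      stop("contour field is on a different grid than the sign map")
    elements <- c(elements, contour_elements(field, style, frame))
  }
  if (!is.null(borders)) {
    for (pl in borders) {
      page <- cbind(frame$tx(pl[, 1]), frame$ty(pl[, 2]))
      elements <- c(elements, svg_polyline(page, "#666666", 1.6))
    }
  }
  finish_svg(frame, elements, file)
}
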