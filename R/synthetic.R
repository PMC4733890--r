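#' Specify one synthetic visual area
#'
#' An area is a cortical polygon together with a differentiable retinotopic
#' mapping from cortical position (mm) to visual field coordinates
#' (eccentricity deg, polar angle deg), a receptive field size model
#' `l = rf_a + rf_b * r` (receptive fields grow with eccentricity, and are
#' larger in higher areas via `rf_a`), and a receptive field scatter
#' standard deviation (deg, applied in flat-chart visual field coordinates).
#' The intended field sign is derived from the mapping's orientation, not
#' asserted.
#'
#' @param name label used in ground-truth scoring (e.g. `"V2"`, `"MT"`).
#' @param polygon k x 2 matrix of cortical vertices, mm (closed implicitly).
#' @param map `function(x, y)` returning a 2-column matrix/cbind of
#'   `(r, theta)` in deg.
#' @param scatter_sd receptive field scatter, deg; default 0.
#' @param rf_a,rf_b receptive field size model intercept (deg) and slope.
#' @param rf_aspect ellipse width/length ratio; default 0.7.
#' @return list of class `area_spec` with the derived `sign` field
#'   (`+1` nonmirror, `-1` mirror).
#' @export
area_spec <- function(name, polygon, map, scatter_sd = 0,
                      rf_a = 2, rf_b = 0.15, rf_aspect = 0.7) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3, is.function(map))
  spec <- structure(list(name = name, polygon = polygon, map = map,
                         scatter_sd = scatter_sd, rf_a = rf_a, rf_b = rf_b,
                         rf_aspect = rf_aspect, sign = NA_integer_),
                    class = "area_spec")
  spec$sign <- truth_field_sign(spec)
  spec
}

#' Ground-truth field sign of an area's retinotopic mapping
#'
#' The field sign is the orientation of the cortex-to-hemifield-chart
#' mapping viewed from the cortical surface (right-hemisphere, y-up
#' convention): the sign of the Jacobian determinant of `(r, theta)` with
#' respect to `(x, y)`. A negative determinant means the polar-angle
#' gradient lies a clockwise quarter-turn from the eccentricity gradient
#' (`lambda` in `(0, pi)`): a nonmirror image representation (`+1`).
#' A positive determinant means mirror image (`-1`). The determinant is
#' evaluated numerically at a lattice of interior points; a sign change or
#' a near-zero determinant anywhere raises a degenerate-mapping error.
#'
#' @param spec an [area_spec()] (the `sign` field is ignored).
#' @param n lattice resolution per axis for probing; default 15.
#' @param h central-difference step, mm.
#' @return `+1` (nonmirror) or `-1` (mirror).
#' @export
truth_field_sign <- function(spec, n = 15, h = 1e-4) {
  poly <- spec$polygon
  xs <- seq(min(poly[, 1]), max(poly[, 1]), length.out = n + 2)[2:(n + 1)]
  ys <- seq(min(poly[, 2]), max(poly[, 2]), length.out = n + 2)[2:(n + 1)]
  px <- rep(xs, times = n); py <- rep(ys, each = n)
  inside <- point_in_polygon(px, py, poly)
  px <- px[inside]; py <- py[inside]
  if (length(px) == 0) stop("no interior probe points in polygon")
  mxp <- spec$map(px + h, py); mxm <- spec$map(px - h, py)
  myp <- spec$map(px, py + h); mym <- spec$map(px, py - h)
  drdx <- (mxp[, 1] - mxm[, 1]) / (2 * h)
  dtdx <- (mxp[, 2] - mxm[, 2]) / (2 * h)
  drdy <- (myp[, 1] - mym[, 1]) / (2 * h)
  dtdy <- (myp[, 2] - mym[, 2]) / (2 * h)
  detj <- drdx * dtdy - drdy * dtdx
  scale <- stats::median(abs(detj))
  if (any(abs(detj) < 1e-8 * max(1, scale)))
    stop("degenerate mapping: Jacobian determinant vanishes inside polygon")
  if (length(unique(sign(detj))) != 1)
    stop("degenerate mapping: Jacobian determinant changes sign")
  if (detj[1] < 0) 1L else -1L
}

# even-odd ray casting; points on the boundary count as inside
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    if (len2 > 0) {
      t <- ((px - xi) * dx + (py - yi) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
      boundary <- boundary | d2 < 1e-18
    }
    j <- i
  }
  inside | boundary
}

#' Assemble a synthetic cortex
#'
#' @param areas list of [area_spec()]s whose polygons tile their union
#'   without overlap.
#' @param borders list of 2-column polyline matrices (mm): the true borders
#'   between adjacent opposite-sign areas.
#' @param seed integer recorded as the cortex's base seed.
#' @return list of class `synthetic_cortex`.
#' @export
synthetic_cortex <- function(areas, borders = list(), seed = 1L) {
  stopifnot(length(areas) >= 1,
            all(vapply(areas, inherits, logical(1), "area_spec")))
  structure(list(areas = areas, borders = borders, seed = as.integer(seed)),
            class = "synthetic_cortex")
}

#' @export
print.synthetic_cortex <- function(x, ...) {
  cat(sprintf("synthetic_cortex: %d areas (%s), %d true borders, seed %d\n",
              length(x$areas),
              paste(vapply(x$areas, function(a)
                sprintf("%s:%+d", a$name, a$sign), ""), collapse = ", "),
              length(x$borders), x$seed))
  invisible(x)
}

#' Stack of alternating-sign strip areas
#'
#' Builds the default synthetic geography: `n_strips` parallel strips
#' stacked along y (like the V2 / DLp / DLi / DLa / MT corridor, where
#' adjoining areas alternate between mirror and nonmirror image maps).
#' Eccentricity increases linearly along x in every strip (a shared
#' eccentricity gradient); polar angle sweeps across each strip along y,
#' reversing direction at every strip border, so that the mapping is
#' continuous across borders and the Jacobian orientation alternates.
#' Strip parameters can also be loaded from a key-value config file
#' (see [read_cortex_config()]).
#'
#' @param n_strips number of strips (2-6 are sensible); default 5.
#' @param names area labels, recycled/truncated to `n_strips`.
#' @param width cortical extent along x, mm; default 12.
#' @param strip_height height of each strip along y, mm; default 2.
#' @param r_range eccentricity at `x = 0` and `x = width`, deg; default
#'   `c(2, 50)` (center-of-gaze to far periphery, as in owl monkey maps).
#' @param theta_range polar angle swept across each strip, deg; default
#'   `c(-80, 80)` (reversals short of the meridians, since receptive field
#'   centers rarely reach them).
#' @param scatter_sd receptive field scatter passed to every strip, deg.
#' @param rf_a,rf_b receptive field size model.
#' @param seed recorded base seed.
#' @return a `synthetic_cortex` whose true borders are the horizontal lines
#'   between strips.
#' @export
strip_cortex <- function(n_strips = 5,
                         names = c("V2", "DLp", "DLi", "DLa", "MT"),
                         width = 12, strip_height = 2,
                         r_range = c(2, 50), theta_range = c(-80, 80),
                         scatter_sd = 0, rf_a = 2, rf_b = 0.15, seed = 1L) {
  stopifnot(n_strips >= 1, width > 0, strip_height > 0)
  names <- rep_len(names, n_strips)
  areas <- vector("list", n_strips)
  for (k in seq_len(n_strips)) {
    y0 <- (k - 1) * strip_height
    y1 <- k * strip_height
    poly <- rbind(c(0, y0), c(width, y0), c(width, y1), c(0, y1))
    up <- k %% 2 == 0  # even strips sweep theta upward with y (V2 nonmirror)
    map <- local({
      y0_ <- y0; up_ <- up; w_ <- width; h_ <- strip_height
      r0 <- r_range[1]; r1 <- r_range[2]
      t0 <- theta_range[1]; t1 <- theta_range[2]
      function(x, y) {
        t <- (y - y0_) / h_
        th <- if (up_) t0 + (t1 - t0) * t else t1 - (t1 - t0) * t
        cbind(r0 + (r1 - r0) * x / w_, th)
      }
    })
    areas[[k]] <- area_spec(names[k], poly, map, scatter_sd = scatter_sd,
                            rf_a = rf_a, rf_b = rf_b)
  }
  borders <- lapply(seq_len(n_strips - 1), function(k) {
    cbind(x = c(0, width), y = rep(k * strip_height, 2))
  })
  synthetic_cortex(areas, borders, seed = seed)
}

#' Single conformal (log-polar) area
#'
#' One rectangular area carrying the classic complex-logarithm retinotopic
#' model: eccentricity grows exponentially along x
#' (`r = r0 * exp(x / k_mag)`, the inverse of logarithmic cortical
#' magnification) and polar angle is linear in y. The eccentricity and
#' polar-angle gradients are everywhere orthogonal, so the noiseless field
#' sign angle `lambda` is exactly 90 deg (nonmirror) or 270 deg (mirror)
#' at every point.
#'
#' @param width,height cortical extent, mm; default 8 x 8.
#' @param r0 eccentricity at `x = 0`, deg; default 2.
#' @param k_mag magnification length constant, mm; default 2.5.
#' @param theta_gain polar angle per mm of y, deg/mm; default 10
#'   (`theta` spans +/-40 deg over the default height).
#' @param sign `+1` nonmirror (default) or `-1` mirror.
#' @param name area label; default `"MT"`.
#' @param scatter_sd,rf_a,rf_b as in [area_spec()].
#' @param seed recorded base seed.
#' @return a `synthetic_cortex` with one area and no internal borders.
#' @export
conformal_cortex <- function(width = 8, height = 8, r0 = 2, k_mag = 2.5,
                             theta_gain = 10, sign = 1L, name = "MT",
                             scatter_sd = 0, rf_a = 2, rf_b = 0.15,
                             seed = 1L) {
  stopifnot(sign %in% c(-1L, 1L))
  poly <- rbind(c(0, 0), c(width, 0), c(width, height), c(0, height))
  yc <- height / 2
  map <- function(x, y) {
    cbind(r0 * exp(x / k_mag), -sign * theta_gain * (y - yc))
  }
  synthetic_cortex(list(area_spec(name, poly, map, scatter_sd = scatter_sd,
                                  rf_a = rf_a, rf_b = rf_b)),
                   borders = list(), seed = seed)
}

#' True sign labels of a synthetic cortex on a grid
#'
#' @param cortex a `synthetic_cortex`.
#' @param field any object with a `geometry` element (e.g. a `grid_field`).
#' @return integer matrix (`+1` / `-1` inside areas, `0` outside).
#' @export
truth_grid <- function(cortex, field) {
  g <- field$geometry
  ax <- grid_axes(list(geometry = g))
  cx <- rep(ax$x, times = g$ny)
  cy <- rep(ax$y, each = g$nx)
  out <- rep(0L, length(cx))
  for (a in cortex$areas) {
    inside <- out == 0L & point_in_polygon(cx, cy, a$polygon)
    out[inside] <- a$sign
  }
  matrix(out, g$nx, g$ny)
}

#' Simulate electrode-row penetration sampling
#'
#' Lays a lattice of penetrations over the cortex -- long rows along x at
#' `within_row_spacing`, rows separated by `row_spacing` along y, covering
#' the bounding box of the area polygons inclusive of both borders (0.5 mm
#' spacing both ways gives at least 4 penetrations per mm^2). Each
#' penetration inside an area reads that area's mapping, receives
#' independent Gaussian receptive field scatter in flat-chart visual field
#' coordinates, and an ellipse from the area's size model (oriented
#' circumferentially). All randomness flows from `seed`; the same seed
#' reproduces the table exactly.
#'
#' @param cortex a `synthetic_cortex`.
#' @param row_spacing,within_row_spacing mm, `> 0`.
#' @param scatter_sd optional override (deg) of each area's scatter.
#' @param seed integer; default the cortex's recorded seed.
#' @return an [rf_table()] (right-hemisphere, normalized).
#' @export
sample_penetrations <- function(cortex, row_spacing = 0.5,
                                within_row_spacing = 0.5,
                                scatter_sd = NULL, seed = cortex$seed) {
  stopifnot(inherits(cortex, "synthetic_cortex"),
            row_spacing > 0, within_row_spacing > 0)
  if (length(cortex$areas) == 0) stop("empty cortex")
  allpoly <- do.call(rbind, lapply(cortex$areas, function(a) a$polygon))
  xs <- seq(min(allpoly[, 1]), max(allpoly[, 1]), by = within_row_spacing)
  ys <- seq(min(allpoly[, 2]), max(allpoly[, 2]), by = row_spacing)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  area_idx <- rep(0L, length(px))
  for (k in seq_along(cortex$areas)) {
    hit <- area_idx == 0L & point_in_polygon(px, py, cortex$areas[[k]]$polygon)
    area_idx[hit] <- k
  }
  keep <- area_idx > 0L
  px <- px[keep]; py <- py[keep]; area_idx <- area_idx[keep]
  n <- length(px)
  if (n == 0) stop("no penetrations fall inside the cortex")
  set.seed(seed)
  r <- theta <- l <- w <- phi <- numeric(n)
  for (k in sort(unique(area_idx))) {
    a <- cortex$areas[[k]]
    sel <- which(area_idx == k)
    m <- a$map(px[sel], py[sel])
    sd_k <- if (is.null(scatter_sd)) a$scatter_sd else scatter_sd
    rr <- m[, 1]; tt <- m[, 2]
    if (sd_k > 0) {
      # scatter in flat-chart coordinates (left hemifield)
      trad <- tt * pi / 180
      u <- -rr * cos(trad) + stats::rnorm(length(sel), 0, sd_k)
      v <- rr * sin(trad) + stats::rnorm(length(sel), 0, sd_k)
      rr <- sqrt(u^2 + v^2)
      tt <- atan2(v, -u) * 180 / pi
      tt <- pmin(100, pmax(-100, tt))
    }
    r[sel] <- rr
    theta[sel] <- tt
    l[sel] <- a$rf_a + a$rf_b * rr
    w[sel] <- a$rf_aspect * (a$rf_a + a$rf_b * rr)
    phi[sel] <- (tt + 90) %% 180
  }
  rf_table(px, py, r, theta, l, w, phi,
           hemisphere = "right", normalized = TRUE)
}

#' Penetration budget and sampling density arithmetic
#'
#' `penetration_budget()` gives the number of penetrations needed to cover
#' `area_mm2` of cortex on a square lattice with the given spacing
#' (`area / spacing^2`): resolving areal borders at 100 micron resolution
#' over a 400 mm^2 exposure requires about 40,000 penetrations.
#' `grid_density()` gives penetrations per mm^2 (`1 / spacing^2`): 0.5 mm
#' spacing is 4 per mm^2.
#'
#' @param area_mm2 cortical area, mm^2, `> 0`.
#' @param spacing_mm lattice spacing, mm, `> 0`.
#' @return a count (`penetration_budget`) or a density per mm^2
#'   (`grid_density`).
#' @export
penetration_budget <- function(area_mm2, spacing_mm) {
  if (any(area_mm2 <= 0) || any(spacing_mm <= 0))
    stop("area and spacing must be positive")
  area_mm2 / spacing_mm^2
}

#' @rdname penetration_budget
#' @export
grid_density <- function(spacing_mm) {
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  1 / spacing_mm^2
}

#' Read strip-cortex parameters from a key-value config file
#'
#' The packaged default is at
#' `system.file("extdata", "strip_cortex.cfg", package = "vfsmap")`.
#' Recognized keys: `n_strips`, `names` (comma separated), `width`,
#' `strip_height`, `r_min`, `r_max`, `theta_min`, `theta_max`,
#' `scatter_sd`, `rf_a`, `rf_b`, `seed`.
#'
#' @param path config file path.
#' @return a `synthetic_cortex` built by [strip_cortex()].
#' @export
read_cortex_config <- function(path) {
  kv <- read_keyvalue(path)
  getn <- function(key, default) {
    if (!is.null(kv[[key]])) as.numeric(kv[[key]]) else default
  }
  nm <- if (!is.null(kv$names)) trimws(strsplit(kv$names, ",")[[1]]) else
    c("V2", "DLp", "DLi", "DLa", "MT")
  strip_cortex(n_strips = getn("n_strips", 5), names = nm,
               width = getn("width", 12),
               strip_height = getn("strip_height", 2),
               r_range = c(getn("r_min", 2), getn("r_max", 50)),
               theta_range = c(getn("theta_min", -80), getn("theta_max", 80)),
               scatter_sd = getn("scatter_sd", 0),
               rf_a = getn("rf_a", 2), rf_b = getn("rf_b", 0.15),
               seed = as.integer(getn("seed", 1)))
}

# flat "key value" / "key = value" text, '#' comments
read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(sub("=", " ", ln), "\\s+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) >= 2)
      out[[parts[1]]] <- paste(parts[-1], collapse = " ")
  }
  out
}
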