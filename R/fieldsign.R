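#' Estimate cortical gradients of a gridded field
#'
#' Central differences over `+/- step/2`, rounded to whole grid cells, in
#' the x and y directions. A step of 0.5-0.6 mm (about the penetration
#' spacing) suppresses cell-to-cell interpolation noise. Cells whose
#' differencing stencil touches an unsupported cell or the grid edge are
#' excluded (`NA`).
#'
#' @param field a `grid_field` (values in deg).
#' @param step finite-difference span, mm; must be `>= ` the grid spacing.
#' @return A `gradient_field`: list with matrices `gx`, `gy` (deg/mm),
#'   the realized `step_mm` (`2 * h * spacing` for `h` whole cells), and
#'   the grid `geometry`.
#' @export
estimate_gradients <- function(field, step = 0.5) {
  stopifnot(inherits(field, "grid_field"))
  g <- field$geometry
  if (step < g$spacing)
    stop("finite-difference step must be >= the grid spacing")
  h <- max(1L, as.integer(round((step / 2) / g$spacing)))
  v <- field$values
  gx <- gy <- matrix(NA_real_, g$nx, g$ny)
  ix <- (h + 1):(g$nx - h)
  iy <- (h + 1):(g$ny - h)
  if (length(ix) > 0 && g$ny > 0)
    gx[ix, ] <- (v[ix + h, ] - v[ix - h, ]) / (2 * h * g$spacing)
  if (length(iy) > 0 && g$nx > 0)
    gy[, iy] <- (v[, iy + h] - v[, iy - h]) / (2 * h * g$spacing)
  structure(list(gx = gx, gy = gy, step_mm = 2 * h * g$spacing,
                 step_cells = h, geometry = g, quantity = field$quantity),
            class = "gradient_field")
}

#' Local visual field sign angle
#'
#' For each grid cell, computes `lambda`, the clockwise angle from the
#' direction of the eccentricity gradient to the direction of the polar
#' angle gradient, in `[0, 2*pi)`, with the map viewed from the pial surface
#' of a (normalized) right hemisphere with y up. `0 < lambda < pi` signifies
#' a nonmirror image representation of the left hemifield (`lambda` near
#' `pi/2` when locally undistorted); `pi < lambda < 2*pi` signifies a mirror
#' image representation (near `3*pi/2` when undistorted). `lambda` depends
#' only on the two gradient directions, so it is invariant to rotations,
#' translations, and scalings of the cortical coordinates and to adding
#' constants to (or rescaling) the receptive field coordinates.
#'
#' Cells where either gradient magnitude falls below `min_gradient` are
#' flagged (`mag_ok = FALSE`); the angle is numerically unstable where the
#' retinotopic gradients vanish, notably near the center of gaze.
#'
#' @param grad_r,grad_theta `gradient_field`s of the eccentricity and polar
#'   angle grids (same geometry).
#' @param min_gradient magnitude floor, deg/mm.
#' @return A `field_sign_map`: list with `lambda` (radians, `NA` where
#'   either gradient is undefined), `mag_ok` (logical), and `geometry`.
#' @export
field_sign_angle <- function(grad_r, grad_theta, min_gradient = 0.5) {
  stopifnot(inherits(grad_r, "gradient_field"),
            inherits(grad_theta, "gradient_field"))
  if (!same_geometry(grad_r$geometry, grad_theta$geometry))
    stop("gradient fields are on different grids")
  rx <- grad_r$gx; ry <- grad_r$gy
  tx <- grad_theta$gx; ty <- grad_theta$gy
  cross <- rx * ty - ry * tx
  dot <- rx * tx + ry * ty
  lambda <- atan2(-cross, dot) %% (2 * pi)
  lambda[is.na(cross)] <- NA_real_
  mag_ok <- sqrt(rx^2 + ry^2) >= min_gradient &
    sqrt(tx^2 + ty^2) >= min_gradient
  mag_ok[is.na(mag_ok)] <- FALSE
  structure(list(lambda = lambda, mag_ok = mag_ok,
                 geometry = grad_r$geometry,
                 min_gradient = min_gradient),
            class = "field_sign_map")
}

#' @export
print.field_sign_map <- function(x, ...) {
  n <- sum(!is.na(x$lambda))
  cat(sprintf("field_sign_map: %d x %d cells, lambda defined at %d\n",
              x$geometry$nx, x$geometry$ny, n))
  if (!is.null(x$class)) {
    cat(sprintf("  classes: %d nonmirror, %d mirror, %d indeterminate\n",
                sum(x$class == 1L, na.rm = TRUE),
                sum(x$class == -1L, na.rm = TRUE),
                sum(x$class == 0L, na.rm = TRUE)))
  }
  invisible(x)
}

#' Classify field sign and compute sigmoidal shading
#'
#' Fills the discrete sign class and the continuous shade used for display.
#' The shade is an odd sigmoid of `sin(lambda)`,
#' `S(u) = tanh(k u) / tanh(k)`, ranging from -1 (saturated mirror, drawn
#' yellow) through 0 (indeterminate, gray, `lambda` near 0 or `pi`) to +1
#' (saturated nonmirror, blue-purple). A cell is classed nonmirror when
#' `0 < lambda < pi` and `|shade| >` the gray threshold, mirror when
#' `pi < lambda < 2*pi` and `|shade| >` the threshold, and indeterminate
#' otherwise (including cells flagged by the gradient-magnitude floor).
#' A `gray_threshold` of 0 reproduces the binary mirror/nonmirror "first
#' cut" map.
#'
#' @param map a [field_sign_angle()] result.
#' @param gray_threshold `|shade|` below this is indeterminate; default 0.2.
#' @param steepness sigmoid constant `k`; default 2.5.
#' @return the `field_sign_map` with `class` (integer matrix: `+1`
#'   nonmirror, `-1` mirror, `0` indeterminate, `NA` where `lambda` is
#'   undefined) and `shade` (numeric matrix in `[-1, 1]`) filled.
#' @export
classify_sign <- function(map, gray_threshold = 0.2, steepness = 2.5) {
  stopifnot(inherits(map, "field_sign_map"))
  s <- sin(map$lambda)
  shade <- tanh(steepness * s) / tanh(steepness)
  shade[!map$mag_ok] <- 0
  shade[is.na(map$lambda)] <- NA_real_
  cls <- matrix(NA_integer_, map$geometry$nx, map$geometry$ny)
  ok <- !is.na(map$lambda)
  cls[ok] <- 0L
  nonm <- ok & map$mag_ok & map$lambda > 0 & map$lambda < pi &
    abs(shade) > gray_threshold
  mirr <- ok & map$mag_ok & map$lambda > pi & abs(shade) > gray_threshold
  cls[nonm] <- 1L
  cls[mirr] <- -1L
  map$class <- cls
  map$shade <- shade
  map$gray_threshold <- gray_threshold
  map$steepness <- steepness
  map
}

#' Receptive-field-size dependent meridian correction
#'
#' Conservatively pushes each receptive field center toward the nearer
#' meridian (horizontal meridian when `|theta| < 45` deg, else the vertical
#' meridian) by `beta` times the receptive field's half-extent along the
#' circumferential (polar-angle) direction, converted to polar-angle degrees
#' at the center's eccentricity. The push is capped so the center cannot
#' cross the meridian it moves toward; `beta = 0` is the identity. Centers
#' at the center of gaze (`r = 0`) or exactly on the horizontal meridian
#' are not moved. This compensates for reversals that occur when the *edge*
#' rather than the center of a large receptive field reaches a meridian;
#' it shifts polar-angle reversals closer to the meridians but has
#' virtually no effect on visual field sign borders.
#'
#' @param table an [rf_table()].
#' @param beta fraction in `[0, 1]`.
#' @return the corrected [rf_table()].
#' @export
meridian_correct <- function(table, beta) {
  stopifnot(inherits(table, "rf_table"), beta >= 0, beta <= 1)
  if (beta == 0 || nrow(table) == 0) return(table)
  out <- table
  for (i in seq_len(nrow(table))) {
    r <- table$r[i]; th <- table$theta[i]
    if (r <= 0) next
    # ellipse half-extent along the circumferential direction
    gam <- (th + 90 - table$phi[i]) * pi / 180
    a <- table$l[i] / 2; b <- table$w[i] / 2
    ext <- sqrt((a * cos(gam))^2 + (b * sin(gam))^2)
    dth <- beta * ext / (r * pi / 180)
    if (abs(th) < 45) {           # toward the horizontal meridian
      out$theta[i] <- sign(th) * max(0, abs(th) - dth)
    } else {                      # toward the vertical meridian
      out$theta[i] <- sign(th) * min(90, abs(th) + dth)
    }
  }
  as_rf_table(out, hemisphere = attr(table, "hemisphere"),
              normalized = attr(table, "normalized"))
}

#' Interior mask of a field sign map
#'
#' Supported cells at least `margin` mm (Chebyshev distance, whole cells)
#' away from any cell where `lambda` is undefined and from the grid edge.
#' Used to restrict summary statistics to cells free of edge effects from
#' the interpolation support boundary and the differencing stencil. The
#' appropriate margin is the interpolation kernel's reach (see
#' [kernel_reach()]): nearer the support boundary, the one-sided truncation
#' of the Gaussian term against the constant stiffness floor bends the
#' interpolated surface toward the data mean and tilts the gradients.
#'
#' @param map a `field_sign_map`.
#' @param margin mm; default 0.5.
#' @return logical matrix.
#' @export
interior_mask <- function(map, margin = 0.5) {
  g <- map$geometry
  m <- as.integer(ceiling(margin / g$spacing))
  ok <- !is.na(map$lambda)
  for (k in seq_len(m)) ok <- erode3x3(ok)
  ok
}

# one step of 3x3 binary erosion (edges become FALSE)
erode3x3 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  out <- matrix(FALSE, nx, ny)
  if (nx < 3 || ny < 3) return(out)
  i <- 2:(nx - 1); j <- 2:(ny - 1)
  out[i, j] <- mask[i, j] & mask[i - 1, j] & mask[i + 1, j] &
    mask[i, j - 1] & mask[i, j + 1] &
    mask[i - 1, j - 1] & mask[i - 1, j + 1] &
    mask[i + 1, j - 1] & mask[i + 1, j + 1]
  out
}

#' Write a classified field sign map as plain-text matrices
#'
#' Writes three sibling files sharing the grid header: `<base>_lambda.txt`
#' (radians), `<base>_class.txt` (integer codes), `<base>_shade.txt`.
#'
#' @param map a classified `field_sign_map`.
#' @param base path prefix.
#' @return `invisible(base)`.
#' @export
write_field_sign_map <- function(map, base) {
  stopifnot(inherits(map, "field_sign_map"), !is.null(map$class))
  as_field <- function(values, tag) {
    structure(list(values = values, support = !is.na(values),
                   geometry = map$geometry, quantity = tag),
              class = "grid_field")
  }
  write_grid_field(as_field(map$lambda, "lambda_rad"),
                   paste0(base, "_lambda.txt"))
  write_grid_field(as_field(map$class + 0, "sign_class"),
                   paste0(base, "_class.txt"))
  write_grid_field(as_field(map$shade, "shade"),
                   paste0(base, "_shade.txt"))
  invisible(base)
}
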