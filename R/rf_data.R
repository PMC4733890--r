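#' Receptive field tables
#'
#' An `rf_table` holds one row per responsive microelectrode penetration:
#' the cortical recording position `(x, y)` in mm on the flattened cortex,
#' and five receptive field parameters digitized on the plotting sphere --
#' eccentricity `r` (deg from the center of gaze), polar angle `theta`
#' (deg, measured clockwise from the left horizontal meridian: upper
#' quadrant 0..+90, lower quadrant 0..-90), and the receptive field ellipse
#' length `l`, width `w` (deg), and orientation `phi` (deg, same clockwise
#' convention, reduced modulo 180).
#'
#' The hemisphere of origin is carried as an attribute; all analysis
#' functions expect tables normalized to the right-hemisphere / left-hemifield
#' convention (see [normalize_hemisphere()]).
#'
#' @param x,y cortical position, mm.
#' @param r eccentricity, deg, `>= 0`.
#' @param theta polar angle, deg, signed within one hemifield. Values a few
#'   degrees past +/-90 (receptive field centers slightly into the ipsilateral
#'   field) are allowed up to +/-100 and flagged in the `theta_overshoot`
#'   attribute.
#' @param l,w receptive field ellipse length and width, deg, `l >= w >= 0`.
#' @param phi ellipse angle, deg; reduced modulo 180 into `[0, 180)`.
#' @param id optional integer penetration labels; must be unique. Defaults to
#'   the row sequence.
#' @param hemisphere `"left"`, `"right"`, or `"unknown"`.
#' @param normalized logical; `TRUE` once [normalize_hemisphere()] has run.
#' @return A data frame of class `rf_table` with columns
#'   `id, x, y, r, theta, l, w, phi` and attributes `hemisphere`,
#'   `normalized`, `units` (`c(xy = "mm", field = "deg")`) and
#'   `theta_overshoot`.
#' @examples
#' tab <- rf_table(x = 1:3, y = 0, r = c(5, 10, 15), theta = c(-30, 0, 30),
#'                 l = 3, w = 2, phi = 0, hemisphere = "right")
#' tab
#' @export
rf_table <- function(x, y, r, theta, l, w, phi, id = NULL,
                     hemisphere = c("unknown", "right", "left"),
                     normalized = FALSE) {
  hemisphere <- match.arg(hemisphere)
  n <- length(x)
  df <- data.frame(
    id = if (is.null(id)) seq_len(n) else as.integer(id),
    x = as.numeric(x), y = as.numeric(y),
    r = as.numeric(r), theta = as.numeric(theta),
    l = as.numeric(l), w = as.numeric(w), phi = as.numeric(phi)
  )
  if (anyDuplicated(df$id))
    stop("penetration ids must be unique")
  if (n > 0) {
    if (any(!is.finite(as.matrix(df[-1]))))
      stop("rf_table fields must be finite")
    if (any(df$r < 0)) stop("eccentricity r must be >= 0")
    if (any(df$w < 0) || any(df$l < df$w))
      stop("ellipse axes must satisfy l >= w >= 0")
    if (any(abs(df$theta) > 100))
      stop("polar angle theta outside the soft bound [-100, 100]")
    df$phi <- df$phi %% 180
  }
  structure(df,
    class = c("rf_table", "data.frame"),
    hemisphere = hemisphere,
    normalized = isTRUE(normalized),
    theta_overshoot = any(abs(df$theta) > 90),
    units = c(xy = "mm", field = "deg"))
}

#' @export
print.rf_table <- function(x, ...) {
  cat(sprintf("rf_table: %d penetrations, hemisphere=%s%s\n",
              nrow(x), attr(x, "hemisphere"),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  NextMethod()
}

# rebuild an rf_table from a plain data frame, preserving metadata
as_rf_table <- function(df, hemisphere = "unknown", normalized = FALSE) {
  rf_table(df$x, df$y, df$r, df$theta, df$l, df$w, df$phi, id = df$id,
           hemisphere = hemisphere, normalized = normalized)
}

#' Read a receptive field table from an ASCII file
#'
#' The dialect is whitespace-separated numeric columns, one responsive
#' penetration per line, in the order `x y r theta l w phi`; lines starting
#' with `#` are comments. An optional leading integer penetration-id column
#' is auto-detected from the column count (8 columns instead of 7). Header
#' comments of the form `# hemisphere: left` and `# normalized: TRUE`
#' written by [write_rf_table()] are honored.
#'
#' @param path path to an existing file.
#' @param hemisphere optional override of the hemisphere metadata; if `NULL`
#'   (default) the value is taken from a `# hemisphere:` header comment, or
#'   `"unknown"`.
#' @return An [rf_table()]. An empty file yields an empty table.
#' @export
read_rf_table <- function(path, hemisphere = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr_hemi <- "unknown"
  hdr_norm <- FALSE
  for (ln in grep("^\\s*#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("#\\s*hemisphere:\\s*(\\S+)", ln))[[1]]
    if (length(m) == 2) hdr_hemi <- m[2]
    m <- regmatches(ln, regexec("#\\s*normalized:\\s*(\\S+)", ln))[[1]]
    if (length(m) == 2) hdr_norm <- toupper(m[2]) %in% c("TRUE", "YES", "1")
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  data_idx <- which(keep)
  if (length(data_idx) == 0) {
    return(rf_table(numeric(0), numeric(0), numeric(0), numeric(0),
                    numeric(0), numeric(0), numeric(0),
                    hemisphere = if (is.null(hemisphere)) hdr_hemi else hemisphere,
                    normalized = hdr_norm))
  }
  toks <- strsplit(trimws(lines[data_idx]), "\\s+")
  ncols <- lengths(toks)
  if (any(ncols < 7)) {
    bad <- data_idx[which(ncols < 7)[1]]
    stop(sprintf("line %d: expected >= 7 whitespace-separated fields, found %d",
                 bad, ncols[which(ncols < 7)[1]]))
  }
  has_id <- ncols[1] >= 8
  want <- if (has_id) 8L else 7L
  vals <- matrix(NA_real_, length(toks), want)
  for (i in seq_along(toks)) {
    v <- suppressWarnings(as.numeric(toks[[i]][seq_len(want)]))
    if (anyNA(v)) {
      col <- which(is.na(v))[1]
      stop(sprintf("line %d, field %d: malformed numeric value '%s'",
                   data_idx[i], col, toks[[i]][col]))
    }
    vals[i, ] <- v
  }
  if (has_id) {
    id <- vals[, 1]; vals <- vals[, -1, drop = FALSE]
  } else id <- NULL
  rf_table(vals[, 1], vals[, 2], vals[, 3], vals[, 4],
           vals[, 5], vals[, 6], vals[, 7], id = id,
           hemisphere = if (is.null(hemisphere)) hdr_hemi else hemisphere,
           normalized = hdr_norm)
}

#' Write a receptive field table to an ASCII file
#'
#' Writes the table in the dialect read by [read_rf_table()], with a header
#' comment recording the column order and hemisphere metadata. Numeric values
#' are written with enough digits (`%.15g`) to round-trip exactly.
#'
#' @param table an [rf_table()].
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_rf_table <- function(table, path) {
  stopifnot(inherits(table, "rf_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# receptive field table",
    "# columns: id x y r theta l w phi",
    paste0("# hemisphere: ", attr(table, "hemisphere")),
    paste0("# normalized: ", isTRUE(attr(table, "normalized"))),
    "# units: x y in mm; r theta l w phi in deg"), con)
  if (nrow(table) > 0) {
    fmt <- function(v) sprintf("%.15g", v)
    writeLines(paste(table$id, fmt(table$x), fmt(table$y), fmt(table$r),
                     fmt(table$theta), fmt(table$l), fmt(table$w),
                     fmt(table$phi)), con)
  }
  invisible(path)
}

#' Normalize a table to the right-hemisphere convention
#'
#' All analyses use a single presentation: cortex viewed from the pial
#' surface of a right hemisphere, receptive fields in the left hemifield.
#' Left-hemisphere tables are mirrored by reflecting cortical `x` about the
#' mid-range of `x` in the table. The per-hemifield angular convention
#' (polar angle measured from the horizontal meridian, positive toward the
#' upper field) is mirror-symmetric, so `r`, `theta`, and `phi` are already
#' expressed in the mirrored frame and are left unchanged. Right-hemisphere
#' tables pass through untouched. Applying the function twice equals
#' applying it once.
#'
#' @param table an [rf_table()] with known hemisphere.
#' @return The normalized [rf_table()] (hemisphere `"right"`,
#'   `normalized = TRUE`).
#' @export
normalize_hemisphere <- function(table) {
  stopifnot(inherits(table, "rf_table"))
  hemi <- attr(table, "hemisphere")
  if (hemi == "unknown")
    stop("hemisphere is unknown; set it before normalizing")
  if (hemi == "right" || isTRUE(attr(table, "normalized")))
    return(as_rf_table(table, hemisphere = "right", normalized = TRUE))
  mid <- (min(table$x) + max(table$x)) / 2
  out <- table
  out$x <- 2 * mid - out$x
  as_rf_table(out, hemisphere = "right", normalized = TRUE)
}

#' Circumferential stretch factor of the flat hemifield chart
#'
#' The flat chart represents radial distances from the center of gaze
#' faithfully (a polar azimuthal-equidistant projection of the plotting
#' sphere), so circumferential distances are stretched by
#' `f(r) = r_rad / sin(r_rad)` where `r_rad` is eccentricity in radians:
#' no distortion at the center of gaze, rising to `pi/2` (about 1.57x) at
#' 90 deg eccentricity.
#'
#' @param r eccentricity in deg, in `[0, 180)`.
#' @return The dimensionless stretch factor, `>= 1`, strictly increasing.
#' @examples
#' flat_correction_factor(c(0, 60, 90))
#' @export
flat_correction_factor <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 180))
    stop("eccentricity must lie in [0, 180]")
  if (any(r == 180)) stop("factor is singular at r = 180 (sin r = 0)")
  rr <- r * pi / 180
  f <- ifelse(rr == 0, 1, rr / sin(rr))
  f
}

#' Flat-correct receptive field ellipses
#'
#' Stretches each receptive field ellipse in the circumferential direction
#' (around the center of gaze) by [flat_correction_factor()] evaluated at its
#' center eccentricity, as required to draw it on the flat hemifield chart.
#' The radial component and the center `(r, theta)` are unchanged. The
#' returned axes keep the `l >= w` convention (axes are swapped, and `phi`
#' rotated by 90, if the stretched circumferential axis overtakes the
#' radial one).
#'
#' @param table an [rf_table()], or any data frame with columns
#'   `r, theta, l, w, phi`.
#' @return A data frame with columns `l`, `w`, `phi` holding the corrected
#'   ellipse for each record.
#' @export
flat_correct_rf <- function(table) {
  stopifnot(all(c("r", "theta", "l", "w", "phi") %in% names(table)))
  n <- nrow(table)
  out <- data.frame(l = numeric(n), w = numeric(n), phi = numeric(n))
  if (n == 0) return(out)
  f <- flat_correction_factor(table$r)
  for (i in seq_len(n)) {
    # work in the (radial, circumferential) basis at the RF center
    delta <- (table$phi[i] - table$theta[i]) * pi / 180
    a <- table$l[i] / 2
    b <- table$w[i] / 2
    R <- matrix(c(cos(delta), sin(delta), -sin(delta), cos(delta)), 2, 2)
    N <- diag(c(1, f[i])) %*% R %*% diag(c(a, b))
    sv <- svd(N)
    lnew <- 2 * sv$d[1]
    wnew <- 2 * sv$d[2]
    dnew <- atan2(sv$u[2, 1], sv$u[1, 1]) * 180 / pi
    out$l[i] <- lnew
    out$w[i] <- wnew
    out$phi[i] <- (table$theta[i] + dnew) %% 180
  }
  out
}
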