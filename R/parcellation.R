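#' Segment a field sign map into candidate areas
#'
#' Connected components of uniform, non-indeterminate sign class form the
#' quantitative "first cut" of the cortex into candidate visual areas.
#' Components are grown with 4-connectivity (diagonal contacts do not join,
#' so opposite-sign regions cannot tunnel through a corner; set
#' `connectivity = 8` to relax). Components smaller than `min_area` are
#' dropped back to unassigned. Labels are assigned in row-major discovery
#' order (x fastest, then y), so the labeling is deterministic.
#'
#' Border polylines are traced along the cell edges separating cells that
#' belong to labeled regions of *opposite* sign (half-cell resolution).
#' With `max_gap = 1`, opposite-sign regions separated by a single
#' unassigned cell (e.g. a one-cell indeterminate seam along a strong
#' reversal) contribute the mid-line of the gap cell instead.
#'
#' @param map a classified `field_sign_map` (see [classify_sign()]).
#' @param min_area minimum region area, mm^2.
#' @param connectivity 4 (default) or 8.
#' @param max_gap 0 or 1 unassigned cells allowed between opposite-sign
#'   cells when tracing borders; default 1.
#' @return A `parcellation`: list with `labels` (integer matrix, 0 =
#'   unassigned), `regions` (data frame: label, sign, n_cells, area_mm2),
#'   `borders` (list of 2-column polyline matrices in mm, each with
#'   attribute `"pair"` naming the two region labels), and `geometry`.
#' @export
segment_sign_map <- function(map, min_area = 0, connectivity = 4,
                             max_gap = 1) {
  stopifnot(inherits(map, "field_sign_map"), !is.null(map$class))
  stopifnot(connectivity %in% c(4, 8), max_gap %in% c(0, 1))
  g <- map$geometry
  cls <- map$class
  cls[is.na(cls)] <- 0L
  labels <- matrix(0L, g$nx, g$ny)
  nxt <- 0L
  offs <- if (connectivity == 4) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    lapply(seq_len(9), function(k) {
      c(((k - 1) %% 3) - 1L, ((k - 1) %/% 3) - 1L)
    })[-5]
  }
  min_cells <- ceiling(min_area / g$spacing^2)
  sizes <- integer(0); signs <- integer(0)
  for (iy in seq_len(g$ny)) for (ix in seq_len(g$nx)) {
    if (cls[ix, iy] == 0L || labels[ix, iy] != 0L) next
    nxt <- nxt + 1L
    sgn <- cls[ix, iy]
    # flood fill
    qx <- integer(256); qy <- integer(256)
    qx[1] <- ix; qy[1] <- iy
    head <- 1L; tail <- 1L
    labels[ix, iy] <- nxt
    count <- 0L
    while (head <= tail) {
      px <- qx[head]; py <- qy[head]; head <- head + 1L
      count <- count + 1L
      for (o in offs) {
        nx_ <- px + o[1]; ny_ <- py + o[2]
        if (nx_ < 1L || nx_ > g$nx || ny_ < 1L || ny_ > g$ny) next
        if (labels[nx_, ny_] == 0L && cls[nx_, ny_] == sgn) {
          labels[nx_, ny_] <- nxt
          tail <- tail + 1L
          if (tail > length(qx)) {
            qx <- c(qx, integer(length(qx)))
            qy <- c(qy, integer(length(qy)))
          }
          qx[tail] <- nx_; qy[tail] <- ny_
        }
      }
    }
    sizes <- c(sizes, count); signs <- c(signs, sgn)
  }
  # drop small regions, then relabel compactly in discovery order
  keep <- sizes >= max(1L, min_cells)
  remap <- integer(length(sizes))
  remap[keep] <- seq_len(sum(keep))
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  regions <- data.frame(label = seq_len(sum(keep)),
                        sign = signs[keep],
                        n_cells = sizes[keep])
  regions$area_mm2 <- regions$n_cells * g$spacing^2
  borders <- trace_borders(labels, regions, g, max_gap)
  structure(list(labels = labels, regions = regions, borders = borders,
                 geometry = g),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d regions, %d border polylines\n",
              nrow(x$regions), length(x$borders)))
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

# collect unit border segments between opposite-sign labeled cells and
# chain them into polylines, grouped by region pair
trace_borders <- function(labels, regions, g, max_gap) {
  sgn <- integer(max(labels, 1L))
  sgn[regions$label] <- regions$sign
  ax_x <- g$origin[1] + (seq_len(g$nx) - 1) * g$spacing
  ax_y <- g$origin[2] + (seq_len(g$ny) - 1) * g$spacing
  h <- g$spacing / 2
  seg <- list()
  add_seg <- function(x1, y1, x2, y2, a, b) {
    pair <- paste(sort(c(a, b)), collapse = "|")
    seg[[length(seg) + 1L]] <<- c(x1, y1, x2, y2, a, b)
    names(seg)[length(seg)] <<- pair
  }
  opp <- function(a, b) a > 0L && b > 0L && a != b && sgn[a] * sgn[b] < 0L
  for (iy in seq_len(g$ny)) for (ix in seq_len(g$nx)) {
    a <- labels[ix, iy]
    # edge between (ix,iy) and (ix+1,iy): vertical segment
    if (ix < g$nx) {
      b <- labels[ix + 1L, iy]
      if (opp(a, b))
        add_seg(ax_x[ix] + h, ax_y[iy] - h, ax_x[ix] + h, ax_y[iy] + h, a, b)
    }
    if (max_gap == 1 && ix < g$nx - 1L && a > 0L && labels[ix + 1L, iy] == 0L) {
      b <- labels[ix + 2L, iy]
      if (opp(a, b))
        add_seg(ax_x[ix + 1L], ax_y[iy] - h, ax_x[ix + 1L], ax_y[iy] + h, a, b)
    }
    # edge between (ix,iy) and (ix,iy+1): horizontal segment
    if (iy < g$ny) {
      b <- labels[ix, iy + 1L]
      if (opp(a, b))
        add_seg(ax_x[ix] - h, ax_y[iy] + h, ax_x[ix] + h, ax_y[iy] + h, a, b)
    }
    if (max_gap == 1 && iy < g$ny - 1L && a > 0L && labels[ix, iy + 1L] == 0L) {
      b <- labels[ix, iy + 2L]
      if (opp(a, b))
        add_seg(ax_x[ix] - h, ax_y[iy + 1L], ax_x[ix] + h, ax_y[iy + 1L], a, b)
    }
  }
  if (length(seg) == 0) return(list())
  out <- list()
  for (pair in unique(names(seg))) {
    segs <- seg[names(seg) == pair]
    for (pl in chain_segments(segs)) {
      attr(pl, "pair") <- as.integer(strsplit(pair, "\\|")[[1]])
      out[[length(out) + 1L]] <- pl
    }
  }
  out
}

# chain unit segments sharing endpoints into polylines (deterministic)
chain_segments <- function(segs) {
  m <- do.call(rbind, lapply(segs, function(s) s[1:4]))
  key <- function(x, y) sprintf("%.6f,%.6f", x, y)
  ends <- cbind(key(m[, 1], m[, 2]), key(m[, 3], m[, 4]))
  used <- rep(FALSE, nrow(m))
  # adjacency: endpoint key -> segment indices
  adj <- split(rep(seq_len(nrow(m)), 2), c(ends[, 1], ends[, 2]))
  deg <- lengths(adj)
  polylines <- list()
  repeat {
    avail <- which(!used)
    if (length(avail) == 0) break
    # prefer starting at an endpoint of odd degree (a polyline end)
    start <- NA_integer_
    for (i in avail) {
      if (deg[[ends[i, 1]]] %% 2 == 1 || deg[[ends[i, 2]]] %% 2 == 1) {
        start <- i; break
      }
    }
    if (is.na(start)) start <- avail[1]
    i <- start
    used[i] <- TRUE
    # orient so we walk away from an odd-degree end if possible
    if (deg[[ends[i, 2]]] %% 2 == 1 && deg[[ends[i, 1]]] %% 2 == 0) {
      pts <- rbind(m[i, 3:4], m[i, 1:2])
    } else {
      pts <- rbind(m[i, 1:2], m[i, 3:4])
    }
    repeat {
      k <- key(pts[nrow(pts), 1], pts[nrow(pts), 2])
      cand <- adj[[k]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      j <- cand[1]
      used[j] <- TRUE
      nxt_pt <- if (ends[j, 1] == k) m[j, 3:4] else m[j, 1:2]
      pts <- rbind(pts, nxt_pt)
    }
    dimnames(pts) <- list(NULL, c("x", "y"))
    polylines[[length(polylines) + 1L]] <- pts
  }
  polylines
}

# minimum distance from points (m x 2) to a set of polylines
dist_to_polylines <- function(pts, polylines) {
  if (length(polylines) == 0 || nrow(pts) == 0)
    return(rep(NA_real_, nrow(pts)))
  best <- rep(Inf, nrow(pts))
  for (pl in polylines) {
    if (nrow(pl) == 1) {
      d <- sqrt((pts[, 1] - pl[1, 1])^2 + (pts[, 2] - pl[1, 2])^2)
      best <- pmin(best, d)
      next
    }
    for (s in seq_len(nrow(pl) - 1)) {
      a <- pl[s, ]; b <- pl[s + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 == 0) rep(0, nrow(pts)) else
        pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] +
                         (pts[, 2] - a[2]) * ab[2]) / len2))
      dx <- pts[, 1] - (a[1] + t * ab[1])
      dy <- pts[, 2] - (a[2] + t * ab[2])
      best <- pmin(best, sqrt(dx^2 + dy^2))
    }
  }
  best
}

# all vertices of a list of polylines as an m x 2 matrix
polyline_points <- function(polylines) {
  if (length(polylines) == 0) return(matrix(numeric(0), 0, 2))
  do.call(rbind, polylines)
}

#' Score sign-map recovery against a synthetic ground truth
#'
#' Compares a [segment_sign_map()] result with the generating
#' [synthetic_cortex()]. Reports (a) the fraction of evaluated cells whose
#' recovered class equals the true sign, over supported cells that carry a
#' true sign and lie farther than `exclude_margin` from every true border
#' (indeterminate cells count as incorrect); (b) the mean and maximum
#' distance (mm) from recovered border polyline vertices to the true
#' borders; (c) the recovered versus true region count; and (d) a per-area
#' table of the majority recovered class inside each true area polygon.
#'
#' @param result a `parcellation`.
#' @param truth a `synthetic_cortex`.
#' @param map the classified `field_sign_map` the parcellation came from
#'   (for the class matrix); must share the parcellation's grid.
#' @param exclude_margin mm; default 0.5.
#' @return list with `sign_accuracy`, `n_eval`, `border_mean_mm`,
#'   `border_max_mm`, `n_regions`, `n_true_areas`, `per_area` (data frame),
#'   and `accuracy_defined`.
#' @export
score_recovery <- function(result, truth, map, exclude_margin = 0.5) {
  stopifnot(inherits(result, "parcellation"),
            inherits(truth, "synthetic_cortex"),
            inherits(map, "field_sign_map"))
  if (!same_geometry(result$geometry, map$geometry))
    stop("parcellation and map are on different grids")
  g <- result$geometry
  tg <- truth_grid(truth, list(geometry = g))
  ax <- grid_axes(list(geometry = g))
  cx <- rep(ax$x, times = g$ny)
  cy <- rep(ax$y, each = g$nx)
  dtrue <- dist_to_polylines(cbind(cx, cy), truth$borders)
  dtrue <- matrix(dtrue, g$nx, g$ny)
  eval_cells <- tg != 0L & !is.na(map$class) &
    (is.na(dtrue) | dtrue > exclude_margin)
  n_eval <- sum(eval_cells)
  any_labeled <- any(result$labels > 0L)
  acc <- if (n_eval > 0 && any_labeled)
    mean(map$class[eval_cells] == tg[eval_cells]) else NA_real_
  rec_pts <- polyline_points(result$borders)
  if (nrow(rec_pts) > 0 && length(truth$borders) > 0) {
    db <- dist_to_polylines(rec_pts, truth$borders)
    bmean <- mean(db); bmax <- max(db)
  } else {
    bmean <- NA_real_; bmax <- NA_real_
  }
  per_area <- data.frame(area = vapply(truth$areas, function(a) a$name, ""),
                         true_sign = vapply(truth$areas, function(a) a$sign,
                                            integer(1)),
                         recovered_sign = NA_integer_,
                         cell_accuracy = NA_real_)
  for (k in seq_along(truth$areas)) {
    inside <- point_in_polygon(cx, cy, truth$areas[[k]]$polygon)
    cells <- matrix(inside, g$nx, g$ny) & !is.na(map$class)
    if (any(cells)) {
      cl <- map$class[cells]
      cl <- cl[cl != 0L]
      if (length(cl) > 0)
        per_area$recovered_sign[k] <- as.integer(sign(sum(sign(cl))))
      ev <- cells & eval_cells
      if (any(ev))
        per_area$cell_accuracy[k] <- mean(map$class[ev] == tg[ev])
    }
  }
  list(sign_accuracy = acc, n_eval = n_eval,
       accuracy_defined = !is.na(acc),
       border_mean_mm = bmean, border_max_mm = bmax,
       n_regions = nrow(result$regions),
       n_true_areas = length(truth$areas),
       per_area = per_area)
}
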