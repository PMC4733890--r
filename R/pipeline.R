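#' Run the field sign pipeline on a receptive field table
#'
#' Convenience wrapper chaining the analysis stages on an already-normalized
#' table: interpolate eccentricity and polar angle onto a common grid,
#' estimate finite-difference gradients, compute the field sign angle,
#' classify, and (optionally) segment.
#'
#' @param table a normalized [rf_table()].
#' @param params an [interp_params()] list.
#' @param step finite-difference span, mm.
#' @param min_gradient gradient magnitude floor, deg/mm.
#' @param gray_threshold shade threshold for the indeterminate class
#'   (0 gives the binary first-cut map).
#' @param steepness shade sigmoid constant.
#' @param min_area minimum region area for segmentation, mm^2; `NULL`
#'   skips segmentation.
#' @param grid optional explicit grid geometry (see
#'   [interpolate_to_grid()]).
#' @return list with `ecc`, `pol` (grid_fields), `grad_r`, `grad_theta`,
#'   `map` (classified `field_sign_map`), and `parcellation` (or `NULL`).
#' @examples
#' cortex <- strip_cortex(n_strips = 3, width = 6, seed = 7)
#' tab <- sample_penetrations(cortex)
#' res <- field_sign_pipeline(tab, min_area = 1)
#' res$parcellation$regions
#' @export
field_sign_pipeline <- function(table, params = interp_params(), step = 0.5,
                                min_gradient = 0.5, gray_threshold = 0,
                                steepness = 2.5, min_area = NULL,
                                grid = NULL) {
  stopifnot(inherits(table, "rf_table"))
  if (!isTRUE(attr(table, "normalized")) &&
      attr(table, "hemisphere") != "right")
    stop("table must be hemisphere-normalized first (normalize_hemisphere)")
  pts <- cbind(table$x, table$y)
  ecc <- interpolate_to_grid(pts, table$r, params,
                             quantity = "eccentricity", grid = grid)
  pol <- interpolate_to_grid(pts, table$theta, params,
                             quantity = "polar_angle", grid = ecc$geometry)
  gr <- estimate_gradients(ecc, step)
  gt <- estimate_gradients(pol, step)
  fsm <- field_sign_angle(gr, gt, min_gradient = min_gradient)
  fsm <- classify_sign(fsm, gray_threshold = gray_threshold,
                       steepness = steepness)
  parc <- if (!is.null(min_area)) segment_sign_map(fsm, min_area = min_area)
  list(ecc = ecc, pol = pol, grad_r = gr, grad_theta = gt,
       map = fsm, parcellation = parc)
}
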