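# shared fixtures built in code

# rebuild an rf_table after mutating columns, keeping the normalized flag
retab <- function(df, hemisphere = "right", normalized = TRUE) {
  rf_table(df$x, df$y, df$r, df$theta, df$l, df$w, df$phi, id = df$id,
           hemisphere = hemisphere, normalized = normalized)
}

# a grid_field holding fn(x, y) on an explicit grid (fully supported)
make_field <- function(fn, origin = c(0, 0), spacing = 0.25, nx = 41,
                       ny = 41, quantity = "eccentricity") {
  xs <- origin[1] + (seq_len(nx) - 1) * spacing
  ys <- origin[2] + (seq_len(ny) - 1) * spacing
  vals <- outer(xs, ys, fn)
  structure(list(values = vals, support = matrix(TRUE, nx, ny),
                 geometry = list(origin = origin, spacing = spacing,
                                 nx = as.integer(nx), ny = as.integer(ny)),
                 quantity = quantity),
            class = "grid_field")
}

# a field_sign_map wrapping a given class matrix (for parcellation tests)
make_sign_map <- function(class_mat, spacing = 0.25) {
  lam <- matrix(pi / 2, nrow(class_mat), ncol(class_mat))
  lam[class_mat == -1L] <- 3 * pi / 2
  lam[is.na(class_mat)] <- NA_real_
  structure(list(lambda = lam, mag_ok = !is.na(class_mat),
                 geometry = list(origin = c(0, 0), spacing = spacing,
                                 nx = nrow(class_mat),
                                 ny = as.integer(ncol(class_mat))),
                 class = class_mat,
                 shade = ifelse(is.na(class_mat), NA_real_,
                                class_mat * 0.9)),
            class = "field_sign_map")
}

# grid geometry mirrored about x = 0, matching grid g cell-for-cell
mirror_grid <- function(g) {
  list(origin = c(-(g$origin[1] + (g$nx - 1) * g$spacing), g$origin[2]),
       spacing = g$spacing, nx = g$nx, ny = g$ny)
}

# small mid-sized strip world used by several tests
small_strip_world <- function(scatter_sd = 1, seed = 11) {
  strip_cortex(n_strips = 3, width = 8, theta_range = c(-75, 75),
               scatter_sd = scatter_sd, seed = seed)
}
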