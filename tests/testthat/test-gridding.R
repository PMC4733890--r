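test_that("constants, single points, and midpoints interpolate exactly", {
  pts <- cbind(runif(20, 0, 2), runif(20, 0, 2))
  f <- interpolate_to_grid(pts, rep(5, 20))
  expect_true(all(abs(f$values[f$support] - 5) < 1e-12))

  single <- interpolate_to_grid(rbind(c(1, 1)), 7)
  expect_true(all(abs(single$values[single$support] - 7) < 1e-12))

  # cell equidistant from values 0 and 10 -> 5
  two <- interpolate_to_grid(rbind(c(0, 0), c(1, 0)), c(0, 10),
                             grid = list(origin = c(0, 0), spacing = 0.25,
                                         nx = 5, ny = 1))
  expect_equal(two$values[3, 1], 5, tolerance = 1e-12)
})

test_that("a densely sampled linear field is reproduced at interior cells", {
  sp <- 0.25
  xs <- seq(0, 8, by = sp)
  pts <- as.matrix(expand.grid(x = xs, y = xs))
  f <- interpolate_to_grid(pts, 2 * pts[, 1],
                           grid = list(origin = c(0, 0), spacing = sp,
                                       nx = length(xs), ny = length(xs)))
  interior <- which(xs >= 3 & xs <= 5)
  ideal <- outer(2 * xs[interior], rep(1, length(interior)))
  expect_equal(f$values[interior, interior], ideal, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("supported values stay within the data range", {
  set.seed(20)
  pts <- cbind(runif(40, 0, 5), runif(40, 0, 5))
  vals <- rnorm(40, 10, 4)
  f <- interpolate_to_grid(pts, vals)
  sup <- f$values[f$support]
  expect_true(all(sup >= min(vals) - 1e-12))
  expect_true(all(sup <= max(vals) + 1e-12))
})

test_that("interpolation is deterministic and validates inputs", {
  set.seed(21)
  pts <- cbind(runif(15), runif(15)); vals <- rnorm(15)
  expect_identical(interpolate_to_grid(pts, vals),
                   interpolate_to_grid(pts, vals))
  expect_error(interpolate_to_grid(pts[0, ], numeric(0)), "at least one")
  expect_error(interpolate_to_grid(pts, vals[-1]), "lengths differ")
  bad <- pts; bad[1, 1] <- NA
  expect_error(interpolate_to_grid(bad, vals), "finite")
})

test_that("raising epsilon stiffens the surface toward the local mean", {
  # a tight cluster with one outlier value at its center
  pts <- rbind(c(0, 0), c(0.5, 0), c(-0.5, 0), c(0, 0.5), c(0, -0.5))
  vals <- c(30, 0, 0, 0, 0)
  at_outlier <- function(eps) {
    f <- interpolate_to_grid(pts, vals, interp_params(epsilon = eps),
                             grid = list(origin = c(0, 0), spacing = 0.25,
                                         nx = 1, ny = 1))
    f$values[1, 1]
  }
  v <- vapply(c(0, 0.1, 0.3, 1), at_outlier, numeric(1))
  expect_true(all(diff(v) < 0))            # monotonically toward the mean
  expect_gt(v[1], mean(vals))
})

test_that("interpolating a sampled cone trims only the peak", {
  xs <- seq(-5, 5, by = 0.5)
  pts <- as.matrix(expand.grid(x = xs, y = seq(-1, 1, by = 0.5)))
  vals <- pmax(0, 10 - abs(pts[, 1]))
  f <- interpolate_to_grid(pts, vals)
  expect_lte(max(f$values, na.rm = TRUE), 10)
  expect_gt(max(f$values, na.rm = TRUE), 8)  # only a little off the peak
})

test_that("support masking matches a brute-force disk count", {
  f <- interpolate_to_grid(rbind(c(0, 0)), 1,
                           interp_params(grid_spacing = 0.5,
                                         support_radius = 1),
                           grid = list(origin = c(-2, -2), spacing = 0.5,
                                       nx = 9, ny = 9))
  # oracle: enumerate the lattice directly
  xs <- seq(-2, 2, by = 0.5)
  oracle <- sum(outer(xs^2, xs^2, "+") <= 1)
  expect_equal(sum(f$support), oracle)

  expect_true(all(mask_support(f, rbind(c(0, 0)), Inf)$support))
  none <- mask_support(f, matrix(numeric(0), 0, 2), 1)
  expect_false(any(none$support))
  expect_true(all(is.na(none$values)))
})

test_that("the kernel cutoff bounds each cell's neighborhood", {
  # two clusters far apart: with the default cutoff each side ignores the
  # other; with cutoff = Inf the epsilon floor mixes them
  pts <- rbind(c(0, 0), c(20, 0))
  vals <- c(0, 10)
  local <- interpolate_to_grid(pts, vals,
                               grid = list(origin = c(0, 0), spacing = 1,
                                           nx = 1, ny = 1))
  expect_equal(local$values[1, 1], 0, tolerance = 1e-12)
  mixed <- interpolate_to_grid(pts, vals,
                               interp_params(cutoff = Inf),
                               grid = list(origin = c(0, 0), spacing = 1,
                                           nx = 1, ny = 1))
  expect_gt(mixed$values[1, 1], 0.5)
  expect_error(interp_params(cutoff = 0.5, support_radius = 1),
               "cutoff")
})

test_that("grid fields round-trip through their text serialization", {
  set.seed(22)
  pts <- cbind(runif(25, 0, 3), runif(25, 0, 3))
  f <- interpolate_to_grid(pts, rnorm(25), quantity = "polar_angle")
  path <- withr::local_tempfile()
  write_grid_field(f, path)
  back <- read_grid_field(path)
  expect_equal(back$values, f$values)
  expect_equal(back$support, f$support)
  expect_equal(back$geometry, f$geometry)
  expect_equal(back$quantity, "polar_angle")
})
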