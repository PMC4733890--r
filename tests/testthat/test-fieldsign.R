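test_that("finite-difference gradients are exact for low-order fields", {
  lin <- make_field(function(x, y) 2 * x)
  g <- estimate_gradients(lin, step = 0.5)
  inner <- 3:39
  expect_equal(g$gx[inner, inner], matrix(2, 37, 37), tolerance = 1e-12)
  expect_equal(g$gy[inner, inner], matrix(0, 37, 37), tolerance = 1e-12)

  const <- make_field(function(x, y) rep(7, length(x)))
  gc <- estimate_gradients(const, step = 0.5)
  expect_equal(gc$gx[inner, inner], matrix(0, 37, 37))

  # central differences of a quadratic are exact: d(x^2)/dx = 2 at x = 1
  quad <- make_field(function(x, y) x^2)
  gq <- estimate_gradients(quad, step = 0.5)
  ix <- 5  # x = 1
  expect_equal(gq$gx[ix, 20], 2, tolerance = 1e-10)

  expect_error(estimate_gradients(lin, step = 0.1), "spacing")
})

test_that("gradient cells with missing stencil neighbors are excluded", {
  f <- make_field(function(x, y) x + y, nx = 11, ny = 11)
  f$values[6, 6] <- NA
  f$support[6, 6] <- FALSE
  g <- estimate_gradients(f, step = 0.5)
  expect_true(is.na(g$gx[5, 6]) && is.na(g$gx[7, 6]))
  expect_true(is.na(g$gy[6, 5]) && is.na(g$gy[6, 7]))
  expect_equal(g$gx[4, 4], 1, tolerance = 1e-12)
})

grad_pair <- function(rx, ry, tx, ty) {
  geo <- list(origin = c(0, 0), spacing = 0.25, nx = 1L, ny = 1L)
  gr <- structure(list(gx = matrix(rx), gy = matrix(ry), step_mm = 0.5,
                       step_cells = 1L, geometry = geo, quantity = "r"),
                  class = "gradient_field")
  gt <- structure(list(gx = matrix(tx), gy = matrix(ty), step_mm = 0.5,
                       step_cells = 1L, geometry = geo, quantity = "t"),
                  class = "gradient_field")
  list(r = gr, t = gt)
}

test_that("lambda is the clockwise angle from grad r to grad theta", {
  gp <- grad_pair(1, 0, 0, -1)
  expect_equal(field_sign_angle(gp$r, gp$t)$lambda[1, 1], pi / 2)
  gp <- grad_pair(1, 0, 0, 1)
  expect_equal(field_sign_angle(gp$r, gp$t)$lambda[1, 1], 3 * pi / 2)
  gp <- grad_pair(1, 0, 1, 0)      # parallel gradients: indeterminate angle
  expect_equal(field_sign_angle(gp$r, gp$t)$lambda[1, 1], 0)
})

test_that("lambda is invariant when both gradients rotate together", {
  set.seed(30)
  for (i in 1:20) {
    a <- runif(1, 0, 2 * pi)
    gr <- c(runif(1, 0.6, 5), runif(1, -2, 2))
    gt <- c(runif(1, -2, 2), runif(1, 0.6, 5))
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    gr2 <- R %*% gr; gt2 <- R %*% gt
    l1 <- field_sign_angle(grad_pair(gr[1], gr[2], gt[1], gt[2])$r,
                           grad_pair(gr[1], gr[2], gt[1], gt[2])$t)
    l2 <- field_sign_angle(grad_pair(gr2[1], gr2[2], gt2[1], gt2[2])$r,
                           grad_pair(gr2[1], gr2[2], gt2[1], gt2[2])$t)
    expect_equal(l1$lambda[1, 1], l2$lambda[1, 1], tolerance = 1e-10)
  }
})

test_that("sub-threshold gradient magnitudes are flagged indeterminate", {
  gp <- grad_pair(0.2, 0, 0, -3)   # grad r below the 0.5 deg/mm floor
  m <- field_sign_angle(gp$r, gp$t)
  expect_false(m$mag_ok[1, 1])
  cls <- classify_sign(m)
  expect_equal(cls$class[1, 1], 0L)
  expect_equal(cls$shade[1, 1], 0)
})

test_that("classification and shading follow the sigmoid of sin(lambda)", {
  gp <- grad_pair(2, 0, 0, -2)     # lambda = 90 deg
  m <- classify_sign(field_sign_angle(gp$r, gp$t))
  expect_equal(m$class[1, 1], 1L)
  expect_equal(m$shade[1, 1], 1)   # tanh(k)/tanh(k) saturates at 1
  gp <- grad_pair(2, 0, 0, 2)      # lambda = 270 deg
  m <- classify_sign(field_sign_angle(gp$r, gp$t))
  expect_equal(m$class[1, 1], -1L)
  expect_equal(m$shade[1, 1], -1)
  gp <- grad_pair(2, 0, -2, 0)     # lambda = pi: sin = 0
  m <- classify_sign(field_sign_angle(gp$r, gp$t))
  expect_equal(m$class[1, 1], 0L)
  expect_equal(m$shade[1, 1], 0, tolerance = 1e-12)
  # intermediate angle: shade strictly between 0 and 1, class by threshold
  gp <- grad_pair(2, 0, 2, -2)     # lambda = 45 deg
  m <- classify_sign(field_sign_angle(gp$r, gp$t))
  expect_equal(m$shade[1, 1], tanh(2.5 * sin(pi / 4)) / tanh(2.5))
  expect_equal(m$class[1, 1], 1L)
})

test_that("meridian correction is capped and vanishes at beta = 0", {
  tab <- rf_table(x = c(0, 1, 2, 3), y = 0, r = c(10, 10, 20, 0),
                  theta = c(-5, 80, 50, 0), l = c(8, 4, 5, 3),
                  w = c(8, 3, 4, 2), phi = 0, hemisphere = "right",
                  normalized = TRUE)
  expect_equal(as.data.frame(meridian_correct(tab, 0)),
               as.data.frame(tab))
  out <- meridian_correct(tab, 1)
  # theta = -5 with a large RF: pushed toward the horizontal meridian but
  # clamped there; never driven to the vertical meridian
  expect_gte(out$theta[1], -5)
  expect_lte(out$theta[1], 0)
  expect_equal(out$theta[1], 0)    # half-extent (4 deg at r=10 -> 23 deg)
  # theta = 80: pushed toward +90, capped at the vertical meridian
  expect_gte(out$theta[2], 80)
  expect_lte(out$theta[2], 90)
  # r = 0 records are never moved
  expect_equal(out$theta[4], 0)
  expect_error(meridian_correct(tab, 1.5))
})

test_that("field sign maps serialize as three sibling matrices", {
  cls <- matrix(c(1L, 1L, -1L, -1L), 2, 2)
  m <- make_sign_map(cls)
  base <- file.path(withr::local_tempdir(), "fs")
  write_field_sign_map(m, base)
  lam <- read_grid_field(paste0(base, "_lambda.txt"))
  cls2 <- read_grid_field(paste0(base, "_class.txt"))
  expect_equal(lam$values, m$lambda)
  expect_equal(cls2$values, matrix(as.numeric(cls), 2, 2))
})
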