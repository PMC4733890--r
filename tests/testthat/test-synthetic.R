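rect_poly <- function(w = 4, h = 4) rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))

test_that("mapping orientation determines the ground-truth field sign", {
  nonm <- area_spec("a", rect_poly(),
                    function(x, y) cbind(2 + 4 * x, -20 * (y - 2)))
  expect_equal(nonm$sign, 1L)
  mirr <- area_spec("b", rect_poly(),
                    function(x, y) cbind(2 + 4 * (4 - x), -20 * (y - 2)))
  expect_equal(mirr$sign, -1L)
  straddle <- rbind(c(-2, 0), c(2, 0), c(2, 4), c(-2, 4))
  expect_error(area_spec("bad", straddle,
                         function(x, y) cbind(x^2, y)), "degenerate")
})

test_that("truth labels agree with the full pipeline on random affine maps", {
  set.seed(40)
  for (i in 1:20) {
    repeat {  # a well-conditioned random affine (r, theta) map whose
              # gradients stay above the indeterminacy floor
      A <- matrix(runif(4, -1, 1), 2, 2)
      if (abs(det(A)) > 0.2 && sqrt(sum(A[1, ]^2)) > 0.3 &&
          sqrt(sum(A[2, ]^2)) > 0.3) break
    }
    map <- function(x, y) cbind(60 + 4 * (A[1, 1] * x + A[1, 2] * y),
                                8 * (A[2, 1] * x + A[2, 2] * y))
    spec <- area_spec(sprintf("a%d", i), rect_poly(5, 5), map)
    cortex <- synthetic_cortex(list(spec), seed = i)
    tab <- sample_penetrations(cortex)
    res <- field_sign_pipeline(tab)
    int <- interior_mask(res$map, 1.5)
    cls <- res$map$class[int]
    cls <- cls[!is.na(cls) & cls != 0L]
    expect_gt(length(cls), 20)
    expect_equal(as.integer(sign(sum(cls))), spec$sign)
  }
})

test_that("penetration lattices have the predicted size and are seeded", {
  cortex <- strip_cortex(n_strips = 1, width = 10, strip_height = 10,
                         seed = 3)
  tab <- sample_penetrations(cortex, 0.5, 0.5)
  expect_equal(nrow(tab), 441)   # 21 x 21 lattice including both borders

  noisy <- strip_cortex(n_strips = 2, width = 6, scatter_sd = 2, seed = 9)
  t1 <- sample_penetrations(noisy)
  t2 <- sample_penetrations(noisy)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- sample_penetrations(noisy, seed = 10)
  expect_false(isTRUE(all.equal(t1$r, t3$r)))
})

test_that("noiseless penetrations lie exactly on the mapping", {
  spec <- area_spec("a", rect_poly(),
                    function(x, y) cbind(2 + 4 * x, -20 * (y - 2)))
  cortex <- synthetic_cortex(list(spec), seed = 2)
  tab <- sample_penetrations(cortex)
  m <- spec$map(tab$x, tab$y)
  expect_equal(tab$r, m[, 1], tolerance = 1e-12)
  expect_equal(tab$theta, m[, 2], tolerance = 1e-12)
  expect_equal(tab$l, 2 + 0.15 * tab$r, tolerance = 1e-12)
  expect_error(sample_penetrations(synthetic_cortex(list(spec)),
                                   row_spacing = 0))
})

test_that("sampling-density arithmetic matches the closed forms", {
  expect_equal(penetration_budget(400, 0.1), 40000)
  expect_equal(grid_density(0.5), 4)
  expect_equal(grid_density(1), 1)
  expect_equal(penetration_budget(1, 0.5), 4)
  expect_error(penetration_budget(-1, 0.5), "positive")
  expect_error(grid_density(0), "positive")
})

test_that("strip cortices alternate sign and record their borders", {
  for (n in c(2, 4, 6)) {
    cx <- strip_cortex(n_strips = n, seed = 1)
    signs <- vapply(cx$areas, function(a) a$sign, integer(1))
    expect_equal(signs, rep_len(c(1L, -1L), n))  # alternation
    expect_equal(length(cx$borders), n - 1)
  }
})

test_that("the packaged config reproduces the default geography", {
  cfg <- system.file("extdata", "strip_cortex.cfg", package = "vfsmap")
  cx <- read_cortex_config(cfg)
  expect_equal(length(cx$areas), 5)
  expect_equal(vapply(cx$areas, function(a) a$name, ""),
               c("V2", "DLp", "DLi", "DLa", "MT"))
  expect_equal(vapply(cx$areas, function(a) a$sign, integer(1)),
               c(1L, -1L, 1L, -1L, 1L))
})

test_that("generator-pipeline closure holds for noiseless strip stacks", {
  for (n in c(2, 4)) {
    cx <- strip_cortex(n_strips = n, width = 8, theta_range = c(-75, 75),
                       seed = n)
    tab <- sample_penetrations(cx)
    res <- field_sign_pipeline(tab, min_area = 2)
    sc <- score_recovery(res$parcellation, cx, res$map)
    expect_equal(sc$n_regions, n)
    expect_equal(sc$per_area$recovered_sign, sc$per_area$true_sign)
    expect_lt(sc$border_mean_mm, 0.25)
  }
})
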