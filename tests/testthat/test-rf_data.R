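test_that("ASCII table lines map directly onto records", {
  path <- withr::local_tempfile()
  writeLines(c("# comment line",
               "12.3 4.5 10.0 -30.0 3.0 2.0 15.0",
               "1.0 2.0 5.0 45.0 2.0 1.0 0.0"), path)
  tab <- read_rf_table(path)
  expect_s3_class(tab, "rf_table")
  expect_equal(nrow(tab), 2)
  expect_equal(unlist(tab[1, -1]),
               c(x = 12.3, y = 4.5, r = 10, theta = -30, l = 3, w = 2,
                 phi = 15))
  expect_equal(tab$id, 1:2)
})

test_that("empty files and parse failures behave as specified", {
  path <- withr::local_tempfile()
  writeLines(character(0), path)
  expect_equal(nrow(read_rf_table(path)), 0)

  writeLines(c("1 2 3 4 5 6 7", "1 2 3 4 5 6"), path)
  expect_error(read_rf_table(path), "line 2")
  writeLines("1 2 3 bogus 5 6 7", path)
  expect_error(read_rf_table(path), "line 1, field 4.*bogus")
  expect_error(read_rf_table(file.path(tempdir(), "does-not-exist.txt")),
               "does-not-exist")
})

test_that("write/read round trip is lossless, id column included", {
  tab <- rf_table(x = c(12.3, -1.5, 0), y = c(4.5, 2, -3),
                  r = c(10, 0.125, 55.5), theta = c(-30, 95, 0.001),
                  l = c(3, 4, 5), w = c(2, 1, 5), phi = c(15, 179, 0),
                  id = c(7L, 9L, 11L), hemisphere = "left")
  path <- withr::local_tempfile()
  write_rf_table(tab, path)
  back <- read_rf_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(attr(back, "hemisphere"), "left")
  expect_identical(back$theta, tab$theta)  # sign preserved exactly
  expect_equal(back$id, c(7L, 9L, 11L))
  # data lines = records, plus header comments
  expect_equal(sum(!grepl("^#", readLines(path))), 3)
})

test_that("rf_table validates its invariants", {
  expect_error(rf_table(0, 0, -1, 0, 2, 1, 0), "r must be")
  expect_error(rf_table(0, 0, 1, 0, 1, 2, 0), "l >= w")
  expect_error(rf_table(0, 0, 1, 105, 2, 1, 0), "soft bound")
  expect_error(rf_table(c(0, 1), c(0, 0), 1, 0, 2, 1, 0, id = c(1, 1)),
               "unique")
  over <- rf_table(0, 0, 1, 95, 2, 1, 0)
  expect_true(attr(over, "theta_overshoot"))
  expect_equal(rf_table(0, 0, 1, 0, 2, 1, 365)$phi, 5)  # phi mod 180
})

test_that("hemisphere normalization mirrors left-hemisphere cortex once", {
  tab <- rf_table(x = c(0, 1, 4), y = c(0, 1, 2), r = c(5, 10, 20),
                  theta = c(10, -20, 30), l = 3, w = 2, phi = 10,
                  hemisphere = "right")
  expect_equal(as.data.frame(normalize_hemisphere(tab)),
               as.data.frame(tab), ignore_attr = TRUE)
  left <- rf_table(x = c(0, 1, 4), y = c(0, 1, 2), r = c(5, 10, 20),
                   theta = c(10, -20, 30), l = 3, w = 2, phi = 10,
                   hemisphere = "left")
  once <- normalize_hemisphere(left)
  expect_equal(once$x, c(4, 3, 0))              # reflected about mid-range
  expect_equal(once$theta, left$theta)          # field coords untouched
  expect_equal(attr(once, "hemisphere"), "right")
  expect_equal(as.data.frame(normalize_hemisphere(once)),
               as.data.frame(once), ignore_attr = TRUE)  # idempotent
  unknown <- rf_table(0, 0, 1, 0, 2, 1, 0)
  expect_error(normalize_hemisphere(unknown), "unknown")
})

test_that("flat correction factor matches its closed form and endpoints", {
  expect_equal(flat_correction_factor(90), pi / 2, tolerance = 1e-12)
  expect_equal(flat_correction_factor(0), 1)
  expect_equal(flat_correction_factor(60), (pi / 3) / sin(pi / 3),
               tolerance = 1e-12)
  expect_equal(round(flat_correction_factor(60), 4), 1.2092)
  # >= 1 and strictly increasing over a 0.1 deg grid
  grid <- seq(0, 179.9, by = 0.1)
  f <- flat_correction_factor(grid)
  expect_true(all(f >= 1))
  expect_true(all(diff(f) > 0))
  expect_error(flat_correction_factor(-1), "\\[0, 180\\]")
  expect_error(flat_correction_factor(181), "\\[0, 180\\]")
  expect_error(flat_correction_factor(180), "singular")
})

test_that("flat correction stretches ellipses circumferentially only", {
  # circular RF at 90 deg: circumferential axis becomes pi/2 x radial axis
  circ <- data.frame(r = 90, theta = 30, l = 4, w = 4, phi = 0)
  out <- flat_correct_rf(circ)
  expect_equal(out$l / out$w, pi / 2, tolerance = 1e-9)
  expect_equal(out$w, 4, tolerance = 1e-9)          # radial axis unchanged
  expect_equal(out$phi, (30 + 90) %% 180, tolerance = 1e-6)
  # any RF at r = 0 is unchanged
  at0 <- data.frame(r = 0, theta = 10, l = 3, w = 2, phi = 40)
  expect_equal(flat_correct_rf(at0), at0[c("l", "w", "phi")],
               tolerance = 1e-12)
  # RF with l along the radial direction at r = 60: w' = f(60) w, l' = l
  rad <- data.frame(r = 60, theta = 25, l = 3, w = 2, phi = 25)
  out2 <- flat_correct_rf(rad)
  expect_equal(out2$l, 3, tolerance = 1e-9)
  expect_equal(out2$w, flat_correction_factor(60) * 2, tolerance = 1e-9)
  expect_equal(out2$phi, 25, tolerance = 1e-6)
})
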