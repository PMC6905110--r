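test_that("density maps integrate to the dot count", {
  hw <- c(128, 128)
  expect_equal(sum(density_from_dots(dot_annotation(NULL, hw))$values), 0)

  one <- density_from_dots(dot_annotation(data.frame(x = 64, y = 64), hw))
  expect_lt(abs(sum(one$values) - 1), 1e-3)
  expect_true(all(one$values >= 0))

  # renormalization keeps unit mass even for dots clipped by the border
  edge <- density_from_dots(dot_annotation(data.frame(x = 0.5, y = 127), hw))
  expect_lt(abs(sum(edge$values) - 1), 1e-3)

  pts <- interior_dots(57, hw, margin = 5, seed = 21)
  many <- density_from_dots(dot_annotation(pts, hw))
  expect_lt(abs(sum(many$values) - 57), 1e-3)

  expect_error(dot_annotation(data.frame(x = 128, y = 5), hw), "outside")
})

test_that("local counts integrate windows exactly (summed-area vs direct)", {
  hw <- c(192, 192)
  dens <- density_from_dots(dot_annotation(interior_dots(20, hw, 10, 3), hw))
  lc <- local_counts(dens)
  # every cell equals naive direct summation over its window
  for (k in withr::with_seed(7, sample(length(lc$values), 12))) {
    ij <- arrayInd(k, dim(lc$values)) - 1L
    direct <- oracle_window_sum(dens$values, ij[1] * 16L, ij[2] * 16L, 64L)
    expect_equal(lc$values[k], direct, tolerance = 1e-12)
  }
})

test_that("uniform density gives the closed-form single-window count", {
  d <- 0.003
  dens <- structure(list(values = matrix(d, 64, 64), sigma = 4),
                    class = "density_map")
  lc <- local_counts(dens, window = 64, stride = 16, pad = 0, context = 0)
  expect_equal(dim(lc$values), c(1L, 1L))
  expect_equal(lc$values[1, 1], 4096 * d)
})

test_that("an interior dot is covered by exactly (window/stride)^2 windows", {
  # the kernel must fit inside every covering window: the dot sits mid-cell
  # and the bandwidth is small enough that 4*sigma stays within the 8-pixel
  # clearance of the worst covering window
  hw <- c(192, 192)
  dens <- density_from_dots(dot_annotation(data.frame(x = 104, y = 104), hw),
                            sigma = 2)
  lc <- local_counts(dens)
  expect_equal(sum(lc$values), 16, tolerance = 0.01)
  expect_equal(sum(lc$values >= 0.99), 16)
  # with the default sigma = 4 the mass is still conserved, merely split
  # across partially covering windows
  d4 <- density_from_dots(dot_annotation(data.frame(x = 104, y = 104), hw))
  expect_equal(sum(local_counts(d4)$values), 16, tolerance = 0.01)
})

test_that("target grid matches the network output geometry", {
  hw <- c(912, 1216)
  dens <- structure(list(values = matrix(0, hw[1], hw[2]), sigma = 4),
                    class = "density_map")
  lc <- local_counts(dens)
  expect_equal(dim(lc$values), c(54L, 73L))
  expect_true(check_target_geometry(lc, canonical_spec("tasselnetv2")))
  bad <- lc
  bad$values <- bad$values[-1, ]
  expect_error(check_target_geometry(bad, canonical_spec("tasselnetv2")),
               "does not match")
})

test_that("conservation: grid sums to (window/stride)^2 x count for interior dots", {
  hw <- c(256, 256)
  for (seed in c(2, 9)) {
    pts <- interior_dots(30, hw, margin = 64, seed = seed)
    lc <- local_counts(density_from_dots(dot_annotation(pts, hw)))
    expect_equal(sum(lc$values) / 16, 30, tolerance = 0.01)
  }
})

test_that("local counts shift by one cell when dots shift by one stride", {
  hw <- c(224, 224)
  pts <- interior_dots(15, hw, margin = 70, seed = 8)
  lc0 <- local_counts(density_from_dots(dot_annotation(pts, hw)))
  pts16 <- data.frame(x = pts$x + 16, y = pts$y + 16)
  lc1 <- local_counts(density_from_dots(dot_annotation(pts16, hw)))
  n <- nrow(lc0$values)
  expect_equal(lc1$values[3:n, 3:n], lc0$values[2:(n - 1), 2:(n - 1)],
               tolerance = 1e-8)
})

test_that("local_counts is linear in the density map", {
  hw <- c(160, 160)
  d1 <- density_from_dots(dot_annotation(interior_dots(8, hw, 10, 1), hw))
  d2 <- density_from_dots(dot_annotation(interior_dots(5, hw, 10, 2), hw))
  mix <- structure(list(values = 2 * d1$values + 3 * d2$values, sigma = 4),
                   class = "density_map")
  expect_equal(local_counts(mix)$values,
               2 * local_counts(d1)$values + 3 * local_counts(d2)$values,
               tolerance = 1e-10)
})

test_that("dot annotations round-trip through CSV and JSON", {
  dots <- data.frame(x = c(1.5, 20, 63.25), y = c(0, 7.75, 40))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_dots_csv(dots, "img.png", csv)
  write_dots_json(dots, "img.png", js)
  expect_equal(read_dots_csv(csv), dots, ignore_attr = TRUE)
  expect_equal(read_dots_json(js), dots, ignore_attr = TRUE)
  expect_equal(attr(read_dots_json(js), "image"), "img.png")
  # empty annotation files are legitimate (zero-count images exist)
  write_dots_csv(dots[0, ], "img.png", csv)
  expect_equal(nrow(read_dots_csv(csv)), 0)
})

test_that("grids persist with their metadata sidecar", {
  hw <- c(160, 160)
  lc <- local_counts(density_from_dots(
    dot_annotation(interior_dots(6, hw, 20, 4), hw)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_grid(lc, path)
  back <- read_grid(path)
  expect_s3_class(back, "local_count_map")
  expect_equal(back$values, lc$values, tolerance = 1e-6)
  expect_equal(back$window, lc$window)
  expect_equal(back$origin_offset, lc$origin_offset)
})
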