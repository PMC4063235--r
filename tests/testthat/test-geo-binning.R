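# Projection, kilometre binning, window extraction and expected counts.

test_that("planar metre inputs are rescaled to kilometres", {
  pts <- data.frame(x = 270000, y = 3290000)
  out <- project_coordinates(pts, mode = "none")
  expect_equal(out$x, 270.0)
  expect_equal(out$y, 3290.0)
})

test_that("equirectangular projection has ~111 km latitude degrees and cosine-shrunk longitude", {
  pts <- data.frame(x = c(-95.4, -95.4), y = c(29.0, 30.0))
  out <- project_coordinates(pts, mode = "equirect")
  expect_equal(diff(out$y), 111, tolerance = 0.005)
  # a degree of longitude near Houston measures about 97 km
  pts2 <- data.frame(x = c(-96, -95), y = c(29.76, 29.76))
  out2 <- project_coordinates(pts2, mode = "equirect")
  expect_equal(diff(out2$x), 96.6, tolerance = 0.01)
})

test_that("UTM projection round-trips within 1 m", {
  lon <- c(-95.4, -95.1, -95.9, -99.0)
  lat <- c(29.76, 29.5, 30.2, 29.9)
  m <- utm_forward(lon, lat, zone = 14)
  back <- utm_inverse(m$x, m$y, zone = 14)
  dm <- geosphere::distGeo(cbind(lon, lat), cbind(back$lon, back$lat))
  expect_lt(max(dm), 1)
})

test_that("projected distances agree with geodesic distances within 1% over a 20 km window", {
  set.seed(4)
  lon <- -95.4 + runif(15, -0.1, 0.1)
  lat <- 29.76 + runif(15, -0.09, 0.09)
  ref <- outer(seq_along(lon), seq_along(lon), function(i, j)
    geosphere::distGeo(cbind(lon[i], lat[i]), cbind(lon[j], lat[j]))) / 1000
  for (mode in c("utm", "equirect")) {
    p <- project_coordinates(data.frame(x = lon, y = lat), mode = mode)
    d <- as.matrix(stats::dist(cbind(p$x, p$y)))
    off <- ref > 0.5  # compare non-trivial separations
    expect_lt(max(abs(d[off] - ref[off]) / ref[off]), 0.01)
  }
})

test_that("degree inputs are validated", {
  expect_error(project_coordinates(data.frame(x = 200, y = 10), "utm"),
               "longitude")
  expect_error(project_coordinates(data.frame(x = 10, y = 95), "equirect"),
               "latitude")
  expect_error(project_coordinates(data.frame(x = NA_real_, y = 1), "none"),
               "finite")
})

test_that("records bin to the nearest integer-km pixel centre", {
  pts <- data.frame(x = c(3.4, 2.6), y = c(7.6, 8.4), VLBW = c(1L, 0L))
  b <- bin_to_pixels(pts)
  expect_equal(nrow(b), 1L)
  expect_equal(b$ix, 3L)
  expect_equal(b$iy, 8L)
  expect_equal(b$n, 2L)
  expect_equal(b$VLBW, 1L)
})

test_that("half-kilometre ties round half to even", {
  b <- bin_to_pixels(data.frame(x = 2.5, y = 2.5))
  expect_equal(c(b$ix, b$iy), c(2L, 2L))
  b2 <- bin_to_pixels(data.frame(x = 3.5, y = 1.5))
  expect_equal(c(b2$ix, b2$iy), c(4L, 2L))
})

test_that("binning conserves records and cases", {
  set.seed(11)
  pts <- data.frame(x = runif(1000, 0, 20), y = runif(1000, 0, 20),
                    VLBW = rbinom(1000, 1, 0.2), LBW = rbinom(1000, 1, 0.5))
  b <- bin_to_pixels(pts)
  expect_equal(sum(b$n), 1000L)
  expect_equal(sum(b$VLBW), sum(pts$VLBW))
  expect_equal(sum(b$LBW), sum(pts$LBW))
})

test_that("study windows have width x height pixels and hold the site pixel at the centre", {
  set.seed(2)
  pts <- data.frame(x = runif(5000, 0, 20), y = runif(5000, 0, 20),
                    VLBW = rbinom(5000, 1, 0.1))
  b <- bin_to_pixels(pts)
  w <- extract_window(b, list(name = "s", x = 10, y = 10))
  expect_equal(w$width * w$height, 400L)
  expect_equal(dim(w$births), c(20L, 20L))
  # a site at (10.2, 10.7) km lives in pixel (10, 11)
  w2 <- extract_window(b, list(name = "s", x = 10.2, y = 10.7))
  expect_equal(w2$origin + c(20 %/% 2, 20 %/% 2), c(10L, 11L))
  # window counts match a direct filter of the binned table
  inside <- b$ix >= w$origin[1] & b$ix < w$origin[1] + 20 &
    b$iy >= w$origin[2] & b$iy < w$origin[2] + 20
  expect_equal(sum(w$births), sum(b$n[inside]))
  expect_equal(sum(w$cases), sum(b$VLBW[inside]))
  # ... and the remainder lives outside: totals are conserved
  expect_equal(sum(w$births) + sum(b$n[!inside]), 5000L)
})

test_that("an empty pixel map yields an all-zero, all-unoccupied window", {
  b <- bin_to_pixels(data.frame(x = numeric(), y = numeric(), VLBW = integer()))
  w <- extract_window(b, list(name = "s", x = 5, y = 5), width = 4, height = 4)
  expect_true(all(w$births == 0))
  expect_true(all(w$occupied == 0))
})

test_that("expected counts are births times the overall rate, zero at structural zeros", {
  rate <- 10803 / 777553
  w <- study_window(births = matrix(c(100, 0, 3, 7), 2, 2))
  w <- compute_expected(w, rate)
  expect_equal(w$expected[1, 1], 1.3893, tolerance = 1e-4)
  expect_equal(w$expected[2, 1], 0)
  expect_equal(sum(w$expected), rate * sum(w$births))
  # E/n is constant across occupied pixels and equals the rate
  occ <- w$births > 0
  expect_true(all(abs(w$expected[occ] / w$births[occ] - rate) < 1e-12))
  expect_error(compute_expected(w, 0), "between 0 and 1")
  expect_error(compute_expected(w, 1.2), "between 0 and 1")
})

test_that("overall rate is the case proportion", {
  pts <- data.frame(x = 0, y = 0, VLBW = 1L)[rep(1, 10), ]
  pts$VLBW <- c(rep(1L, 3), rep(0L, 7))
  expect_equal(overall_rate(pts), 0.3)
  pts$VLBW <- 1L
  expect_equal(overall_rate(pts), 1.0)
  pts$VLBW <- 0L
  expect_equal(overall_rate(pts), 0.0)
  expect_error(overall_rate(pts[0, ]), "at least one record")
})

test_that("window CSV export holds one validated row per pixel", {
  w <- compute_expected(study_window(matrix(c(2, 0, 1, 5), 2, 2),
                                     matrix(c(1, 0, 0, 2), 2, 2)), 0.4)
  f <- tempfile(fileext = ".csv")
  write_window_csv(w, f)
  d <- read.csv(f)
  expect_equal(nrow(d), 4L)
  expect_equal(sum(d$n), 8)
  expect_equal(d$E, d$n * 0.4)
  expect_equal(d$occupied, as.integer(d$n > 0))
})

test_that("point and site readers validate their columns", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1:3, y = 4:6, VLBW = c(0L, 1L, 0L)), f,
            row.names = FALSE)
  expect_equal(nrow(read_points(f)), 3L)
  write.csv(data.frame(a = 1), f, row.names = FALSE)
  expect_error(read_points(f), "columns")
  write.csv(data.frame(name = "s", x = 1, y = 2), f, row.names = FALSE)
  expect_equal(read_sites(f)$name, "s")
})
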