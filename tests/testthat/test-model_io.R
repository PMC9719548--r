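# Domain types and cube/map round trips.

test_that("wavelength grid and spectrum enforce their invariants", {
  expect_error(wavelength_grid(c(500, 501)), "at least 8")
  expect_error(wavelength_grid(c(500, 500.4, 500.4, 501, 502, 503, 504, 505)),
               "strictly increasing")
  expect_error(wavelength_grid(seq(100, 400, by = 10)), "within")
  g <- default_grid()
  expect_length(g$values, 376)
  expect_equal(g$step, 0.4)

  expect_error(spectrum(g, rep(NaN, 376)), "non-finite")
  # negative intensities are clipped, not rejected, with a logged count
  s <- spectrum(g, c(-1, -0.5, rep(1, 374)))
  expect_equal(attr(s, "n_clipped"), 2)
  expect_true(all(s$intensity >= 0))
})

test_that("long-CSV dialect round-trips and counts pixels", {
  g <- wavelength_grid(seq(540, 546, by = 0.4))
  centers <- matrix(c(550, 555, 563, 570), 2, 2)
  cube <- tiny_cube(centers, grid = g)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cube(cube, f, "longcsv")
  back <- read_cube(f, "longcsv")
  expect_equal(prod(dim(back$data)[1:2]), 4)
  expect_equal(back$grid$values, cube$grid$values)
  expect_equal(back$data, cube$data, tolerance = 1e-12)
})

test_that("container dialect round-trips values and metadata", {
  cube <- tiny_cube(matrix(c(550, 560, 570, 580), 2, 2),
                    grid = wavelength_grid(seq(540, 600, by = 2)))
  f <- withr::local_tempfile(fileext = ".json")
  write_cube(cube, f, "container")
  back <- read_cube(f)
  expect_equal(back$data, cube$data)
  expect_equal(back$laser_nm, 532)
  expect_equal(back$pixel_um, 16)
})

test_that("a 60x30 cube on the default grid re-reads with shape (60, 30, 376)", {
  sim <- simulate_cube(uniform_phantom("scc"), seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_cube(sim$cube, f)
  expect_equal(dim(read_cube(f)$data), c(60, 30, 376))
})

test_that("a missing pixel in a declared scan is an error naming it", {
  g <- wavelength_grid(seq(540, 546, by = 0.4))
  cube <- tiny_cube(matrix(555, 3, 3), grid = g)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cube(cube, f, "longcsv")
  dt <- data.table::fread(f)
  data.table::fwrite(dt[!(dt$i == 2 & dt$j == 3), ], f)
  expect_error(read_cube(f, "longcsv"), "\\(2,3\\)")
})

test_that("inconsistent per-pixel wavelength vectors are a grid-mismatch error", {
  g <- wavelength_grid(seq(540, 546, by = 0.4))
  cube <- tiny_cube(matrix(555, 2, 2), grid = g)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cube(cube, f, "longcsv")
  dt <- data.table::fread(f)
  dt$wavelength_nm[dt$i == 2 & dt$j == 2][1] <- 539.0  # different grid
  data.table::fwrite(dt, f)
  expect_error(read_cube(f, "longcsv"), "grid mismatch")
})

test_that("round trip is identity on randomized small cubes in both dialects", {
  set.seed(101)
  for (rep in 1:5) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    g <- wavelength_grid(seq(540, 560, length.out = sample(8:20, 1)))
    arr <- array(runif(m * n * length(g$values)), c(m, n, length(g$values)))
    cube <- spectral_cube(arr, g)
    for (fmt in c("longcsv", "container")) {
      f <- withr::local_tempfile(fileext = if (fmt == "longcsv") ".csv" else ".json")
      write_cube(cube, f, fmt)
      back <- read_cube(f, fmt)
      expect_equal(back$data, cube$data, tolerance = 1e-12)
      expect_equal(back$grid$values, cube$grid$values, tolerance = 1e-12)
    }
  }
})

test_that("validate_cube flags empty spectra and broken grids", {
  cube <- tiny_cube(matrix(c(550, 560, 570, 580), 2, 2),
                    grid = wavelength_grid(seq(540, 600, by = 2)))
  expect_true(validate_cube(cube)$ok)

  cube$data[1, 2, ] <- 0
  rep1 <- validate_cube(cube)
  expect_false(rep1$ok)
  expect_equal(rep1$issues$code, "empty_spectrum")
  expect_equal(rep1$issues[, c("i", "j")], data.frame(i = 1L, j = 2L))

  cube2 <- tiny_cube(matrix(555, 2, 2), grid = wavelength_grid(seq(540, 546, by = 0.4)))
  cube2$grid$values[3] <- cube2$grid$values[2]  # damage after construction
  expect_true("grid_not_increasing" %in% validate_cube(cube2)$issues$code)
})

test_that("map CSV and float TIFF exports round-trip, missing included", {
  map <- matrix(rnorm(60, 560, 5), 6, 10)
  map[2, 3] <- NA
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_map_csv(map, f1)
  expect_equal(read_map_csv(f1), map, tolerance = 1e-12)
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_map_tiff(map, f2)
  back <- read_map_tiff(f2)
  expect_true(is.na(back[2, 3]))
  expect_equal(back, map, tolerance = 1e-5)  # float32 precision
})
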