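# Forward model: class table, intensity/wavelength laws, phantoms, cubes.

test_that("default class table carries the documented spectral parameters", {
  tab <- default_class_table()
  get <- function(lbl, col) tab[[col]][tab$label == lbl]
  expect_equal(get("melanoma", "center_nm"), 550)
  expect_equal(get("nevus", "center_nm"), 581)
  expect_equal(get("scc", "spread_nm"), 3.3)
  expect_equal(tab$center_nm, c(550, 555, 563, 570, 581))
  expect_equal(tab$spread_nm, c(2, 4, 3.3, 4.1, 14.8))
  expect_equal(tab$typ_conc_uM, c(2, 8, 10, 16, 12))
  expect_true(all(tab$band_lo_nm < tab$center_nm & tab$center_nm < tab$band_hi_nm))
})

test_that("quenched intensity law: zero at zero, ambiguity pair, argmax at kappa", {
  expect_equal(intensity_vs_concentration(0), 0)
  expect_error(intensity_vs_concentration(-1), "must be >= 0")
  # kappa = 30/ln 4 makes I(10) and I(40) equal to machine precision
  expect_equal(intensity_vs_concentration(10), intensity_vs_concentration(40))
  # brute-force grid search against the closed-form maximum at c = kappa
  cgrid <- seq(0, 200, by = 1e-3)
  c_hat <- cgrid[which.max(intensity_vs_concentration(cgrid))]
  expect_equal(c_hat, default_quench_uM(), tolerance = 1e-3)
})

test_that("wavelength redshifts monotonically with concentration", {
  tab <- default_calibration()
  expect_equal(wavelength_vs_concentration(2, tab), 550)
  expect_equal(wavelength_vs_concentration(10, tab), 563)
  set.seed(5)
  c1 <- runif(1000, 2, 16); c2 <- runif(1000, 2, 16)
  lo <- pmin(c1, c2); hi <- pmax(c1, c2)
  expect_true(all(wavelength_vs_concentration(lo, tab) <=
                  wavelength_vs_concentration(hi, tab) + 1e-12))
  expect_error(wavelength_vs_concentration(20, tab), "span")
})

test_that("phantom painting follows area arithmetic and list order", {
  ph <- phantom_spec(background = "normal",
                     regions = list(list(i0 = 11, i1 = 20, j0 = 11, j1 = 20,
                                         label = "melanoma")))
  labs <- make_phantom(ph)
  expect_equal(sum(labs == "melanoma"), 100)
  expect_equal(sum(labs == "normal"), 1700)

  expect_equal(unique(as.vector(make_phantom(phantom_spec(background = "scc")))),
               "scc")

  ph2 <- phantom_spec(regions = list(
    list(i0 = 1, i1 = 10, j0 = 1, j1 = 10, label = "bcc"),
    list(i0 = 5, i1 = 10, j0 = 5, j1 = 10, label = "scc")))
  labs2 <- make_phantom(ph2)
  expect_equal(labs2[7, 7], "scc")   # later region wins the overlap
  expect_equal(labs2[2, 2], "bcc")

  expect_error(phantom_spec(regions = list(
    list(i0 = 1, i1 = 99, j0 = 1, j1 = 2, label = "bcc"))), "outside")
})

test_that("phantom JSON dialect uses 0-based half-open rectangles", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"m": 10, "n": 8, "background": "normal",
               "regions": [{"x0": 0, "y0": 0, "x1": 3, "y1": 2,
                            "label": "melanoma"}]}', f)
  labs <- make_phantom(phantom_spec_from_file(f))
  expect_equal(dim(labs), c(10, 8))
  expect_equal(sum(labs == "melanoma"), 6)  # [0,3) x [0,2) = 3 x 2 pixels
  expect_equal(labs[3, 2], "melanoma")
  expect_equal(labs[4, 1], "normal")
})

test_that("noise-free simulation puts every argmax within a grid step of truth", {
  sim <- simulate_cube(uniform_phantom("melanoma", 12, 10), seed = 2)
  wl <- sim$cube$grid$values
  for (k in seq_len(120)) {
    i <- (k - 1) %% 12 + 1; j <- (k - 1) %/% 12 + 1
    lam_hat <- wl[which.max(sim$cube$data[i, j, ])]
    expect_lt(abs(lam_hat - sim$truth$wavelength[i, j]), 0.4 + 1e-12)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  labs <- uniform_phantom("bcc", 10, 6)
  nz <- noise_model("rician", 0.05, relative = TRUE)
  a <- simulate_cube(labs, noise = nz, seed = 99)
  b <- simulate_cube(labs, noise = nz, seed = 99)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(a$truth$wavelength, b$truth$wavelength)
  c2 <- simulate_cube(labs, noise = nz, seed = 100)
  expect_false(identical(a$cube$data, c2$cube$data))
})

test_that("rician noise inflates the mean intensity (magnitude bias)", {
  labs <- uniform_phantom("normal", 40, 25)   # 1000 pixels
  clean <- simulate_cube(labs, seed = 8)
  noisy <- simulate_cube(labs, noise = noise_model("rician", 0.05,
                                                   relative = TRUE), seed = 8)
  wl <- clean$cube$grid$values
  band <- wl > 540 & wl < 600
  # Rician mean exceeds the underlying amplitude, most visibly off-peak
  expect_gt(mean(noisy$cube$data[, , band]), mean(clean$cube$data[, , band]))
})

test_that("dichroic cutoff zeroes the response at and below 535 nm", {
  sim <- simulate_cube(uniform_phantom("scc", 4, 4), seed = 1)
  wl <- sim$cube$grid$values
  expect_true(all(sim$cube$data[, , wl <= 535] == 0))
  expect_true(all(sim$cube$data[, , wl > 560 & wl < 566] > 0))
})

test_that("grid must cover the Rd6G emission region and labels must be known", {
  g_bad <- wavelength_grid(seq(540, 580, by = 0.4))  # stops short of 600
  expect_error(simulate_cube(uniform_phantom("scc", 4, 4), grid = g_bad),
               "540-600")
  expect_error(simulate_cube(matrix("mystery", 4, 4)), "mystery")
})

test_that("sampled class peak distributions only overlap at the nevus/normal boundary", {
  tab <- default_class_table()
  sims <- lapply(tab$label, function(L)
    range(simulate_cube(uniform_phantom(L, 20, 20), seed = 31)$truth$wavelength))
  names(sims) <- tab$label
  # melanoma/bcc/scc/normal are pairwise disjoint
  for (a in c("melanoma", "bcc", "scc")) {
    b <- tab$label[match(a, tab$label) + 1]
    expect_lt(sims[[a]][2], sims[[b]][1])
  }
  # nevus reaches below 575 into the normal side of the boundary
  expect_lt(sims$nevus[1], 575.5)
  expect_gt(sims$nevus[1], sims$normal[1])
})
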