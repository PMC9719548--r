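# Spectral-band segmentation and class summaries.

test_that("default bands route the documented wavelengths", {
  b <- default_bands()
  lam <- c(550, 570, 600, 553, 575.5, 548 - 0.01)
  expect_equal(classify_map(matrix(lam, 1))[1, ],
               c("melanoma", "normal", "unclassified", "bcc", "nevus",
                 "unclassified"))
  # closed-open convention: the lower edge belongs to the band
  expect_equal(classify_map(matrix(559, 1, 1))[1, 1], "scc")
  # together the bands cover [548, 588)
  expect_equal(b$lo_nm[1], 548)
  expect_equal(b$hi_nm[nrow(b)], 588)
  expect_true(all(b$lo_nm[-1] == b$hi_nm[-nrow(b)]))
})

test_that("random disjoint band sets never double-assign", {
  set.seed(50)
  for (rep in 1:20) {
    cuts <- sort(runif(6, 540, 600))
    bands <- class_bands(data.frame(
      label = paste0("c", 1:3),
      lo_nm = cuts[c(1, 3, 5)], hi_nm = cuts[c(2, 4, 6)]))
    lam <- runif(500, 535, 605)
    lab <- classify_map(matrix(lam, 10, 50), bands)
    # recompute membership count per pixel; must be 0 or 1
    hits <- sapply(lam, function(l) sum(l >= bands$lo_nm & l < bands$hi_nm))
    expect_true(all(hits <= 1))
    expect_equal(as.vector(lab) != "unclassified", hits == 1)
  }
  expect_error(class_bands(data.frame(label = c("a", "b"),
                                      lo_nm = c(550, 555),
                                      hi_nm = c(556, 560))), "disjoint")
})

test_that("a noise-free two-region phantom classifies pixel-perfectly", {
  ph <- phantom_spec(background = "normal",
                     regions = list(list(i0 = 1, i1 = 30, j0 = 1, j1 = 30,
                                         label = "melanoma")))
  truth <- make_phantom(ph)
  sim <- simulate_cube(truth, seed = 15)
  labels <- classify_map(build_maps(sim$cube))
  expect_identical(labels, truth)
})

test_that("segmentation is a pure function of the wavelength map", {
  sim <- simulate_cube(uniform_phantom("scc", 10, 10), seed = 16)
  l1 <- classify_map(build_maps(sim$cube))
  sim$cube$data <- sim$cube$data * 0.01
  l2 <- classify_map(build_maps(sim$cube))
  expect_identical(l1, l2)
})

test_that("the 3x3 modal filter corrects a lone misclassified pixel", {
  labels <- matrix("bcc", 9, 9)
  labels[5, 5] <- "scc"
  wl <- matrix(555, 9, 9); wl[5, 5] <- 560
  maps <- pixel_maps(intensity = matrix(1, 9, 9), wavelength = wl)
  fixed <- classify_map(maps, spatial_median = TRUE)
  expect_equal(fixed[5, 5], "bcc")
  expect_true(all(fixed == "bcc"))
  # missing pixels stay missing
  wl[1, 1] <- NA
  maps2 <- pixel_maps(intensity = matrix(1, 9, 9), wavelength = wl)
  expect_equal(classify_map(maps2, spatial_median = TRUE)[1, 1], "missing")
})

test_that("summaries report the class scatter statistics", {
  tab <- default_class_table()
  sim <- simulate_cube(uniform_phantom("nevus"), seed = 17)
  maps <- build_maps(sim$cube)
  labels <- matrix("nevus", 60, 30)  # summarize the known region
  s <- summarize_classes(labels, maps)
  nevus <- s[s$label == "nevus", ]
  expect_equal(nevus$count, 1800)
  expect_equal(nevus$fraction, 1)
  # recovered width of the 14.8 nm spread class, noise-free, n = 1800
  expect_equal(nevus$width_nm, 14.8, tolerance = 0.05)
  expect_equal(nevus$modal_shift_nm, 49)
  expect_equal(nevus$typ_conc_uM, 12)
  expect_equal(s$count[s$label == "melanoma"], 0)
  expect_true(is.na(s$width_nm[s$label == "melanoma"]))
})

test_that("a noise-free melanoma phantom has modal shift 18 nm", {
  sim <- simulate_cube(uniform_phantom("melanoma", 20, 15), seed = 18)
  maps <- build_maps(sim$cube)
  labels <- classify_map(maps)
  s <- summarize_classes(labels, maps)
  expect_equal(s$modal_shift_nm[s$label == "melanoma"], 18)
})

test_that("the scatter table is consistent with the summary and conserves the laser line", {
  sim <- simulate_cube(uniform_phantom("normal"), seed = 19)
  maps <- apply_k(build_maps(sim$cube))
  labels <- classify_map(maps)
  s <- summarize_classes(labels, maps)
  sc <- export_scatter(labels, maps)
  expect_equal(nrow(sc), 1800)
  expect_equal(unique(sc$lambda_nm - sc$shift_nm), 532)
  counts <- table(sc$label)
  for (L in names(counts))
    expect_equal(unname(counts[[L]]), s$count[s$label == L])
})

test_that("classification stays above 99% under 2% rician noise away from band edges", {
  truth <- matrix(rep(c("melanoma", "bcc", "scc", "normal"), each = 450),
                  60, 30)
  sim <- simulate_cube(truth, noise = noise_model("rician", 0.02,
                                                  relative = TRUE), seed = 20)
  sig <- 0.02 * max(sim$truth$intensity)
  labels <- classify_map(build_maps(sim$cube,
                                    preprocess_config(rician_sigma = sig)))
  edges <- sort(unique(c(default_bands()$lo_nm, default_bands()$hi_nm)))
  dist_edge <- apply(abs(outer(as.vector(sim$truth$wavelength), edges, "-")),
                     1, min)
  away <- dist_edge > 0.5
  expect_gt(mean((labels == truth)[away]), 0.99)
})
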