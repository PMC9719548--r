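# Calibration table, inversion, the characteristic operator, intensity
# ambiguity.

test_that("default calibration holds the documented anchors and invariants", {
  tab <- default_calibration()
  expect_equal(tab$anchors$conc_uM, c(2, 8, 10, 16))
  expect_equal(tab$anchors$wavelength_nm, c(550, 555, 563, 570))
  expect_true(all(diff(tab$anchors$conc_uM) > 0))
  expect_true(all(diff(tab$anchors$wavelength_nm) > 0))
  expect_equal(unname(tab$intensity_params["quench_uM"]), 30 / log(4))
  expect_equal(wavelength_vs_concentration(8, tab), 555)  # anchor lookup
  expect_error(calibration_table(data.frame(c = c(2, 8), w = c(555, 550))),
               "increasing")
})

test_that("wavelength inversion is exact at anchors and brackets between them", {
  tab <- default_calibration()
  expect_equal(wavelength_to_concentration(563, tab), 10)
  expect_equal(wavelength_to_concentration(550, tab), 2)
  c560 <- wavelength_to_concentration(560, tab)
  expect_gt(c560, 8); expect_lt(c560, 10)
  # cross-check by manual bisection on the forward curve
  lo <- 8; hi <- 10
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (wavelength_vs_concentration(mid, tab) < 560) lo <- mid else hi <- mid
  }
  expect_equal(c560, (lo + hi) / 2, tolerance = 1e-9)
  expect_error(wavelength_to_concentration(581, tab), "span",
               class = "ssfm_validation_error")
})

test_that("calibration round trip holds to 1e-9 relative across the span", {
  for (interp in c("monotone", "linear")) {
    tab <- calibration_table(default_calibration()$anchors,
                             interpolation = interp)
    set.seed(12)
    cs <- runif(100, 2, 16)
    back <- wavelength_to_concentration(
      wavelength_vs_concentration(cs, tab), tab)
    expect_lt(max(abs(back - cs) / cs), 1e-9)
  }
})

test_that("the identity-scalar operator is c = k * lambda and others are rejected", {
  maps <- pixel_maps(intensity = matrix(1, 2, 2),
                     wavelength = matrix(c(550, 555, 563, 570), 2, 2))
  out <- apply_k(maps, k_operator("identity-scalar", k = 1))
  expect_equal(out$concentration, maps$wavelength)
  out2 <- apply_k(maps, k_operator("identity-scalar", k = 0.5))
  expect_equal(out2$concentration, 0.5 * maps$wavelength)
  expect_error(k_operator("non-diagonal"), class = "ssfm_unsupported_error")
})

test_that("a noise-free uniform SCC scan calibrates to a constant 10 uM map", {
  tab <- class_table_with("scc", spread_nm = 0)
  sim <- simulate_cube(uniform_phantom("scc", 20, 15), classes = tab, seed = 4)
  maps <- apply_k(build_maps(sim$cube))
  expect_equal(unname(as.vector(maps$concentration)), rep(10, 300),
               tolerance = 1e-6)
})

test_that("nevus pixels fall outside the calibration span and go missing", {
  maps <- pixel_maps(intensity = matrix(1, 1, 2),
                     wavelength = matrix(c(581, 563), 1, 2))
  out <- apply_k(maps, k_operator("table"))
  expect_true(is.na(out$concentration[1, 1]))
  expect_equal(out$concentration[1, 2], 10)
  expect_equal(attr(out$concentration, "out_of_span"), 1L)
  # extrapolation keeps them, on the linear end-slope continuation
  out2 <- apply_k(maps, k_operator("table"), extrapolate = TRUE)
  expect_gt(out2$concentration[1, 1], 16)
})

test_that("the concentration map depends only on the wavelength map", {
  sim <- simulate_cube(uniform_phantom("bcc", 10, 10), seed = 13)
  maps1 <- apply_k(build_maps(sim$cube))
  cube2 <- sim$cube
  cube2$data <- cube2$data * 7.3   # rescale all intensities
  maps2 <- apply_k(build_maps(cube2))
  expect_equal(maps2$concentration, maps1$concentration)
  expect_equal(maps2$wavelength, maps1$wavelength)
})

test_that("intensity inversion returns the ambiguity pair and degenerate sets", {
  tab <- default_calibration()
  pair <- concentration_candidates_from_intensity(
    intensity_vs_concentration(10), tab)
  expect_length(pair, 2)
  expect_equal(pair, c(10, 40), tolerance = 1e-6)
  expect_equal(concentration_candidates_from_intensity(0, tab), 0)
  Imax <- intensity_vs_concentration(default_quench_uM())
  expect_length(concentration_candidates_from_intensity(Imax * 1.01, tab), 0)
  expect_equal(concentration_candidates_from_intensity(Imax, tab),
               default_quench_uM())
})

test_that("candidate sets have cardinality <= 2 and bracket the quench constant", {
  tab <- default_calibration()
  kap <- default_quench_uM()
  set.seed(77)
  for (I in runif(50, 0, intensity_vs_concentration(kap) * 1.2)) {
    cand <- concentration_candidates_from_intensity(I, tab)
    expect_lte(length(cand), 2)
    if (length(cand) == 2) {
      expect_lt(cand[1], kap); expect_gt(cand[2], kap)
      expect_equal(intensity_vs_concentration(cand[1]),
                   intensity_vs_concentration(cand[2]), tolerance = 1e-9)
    }
  }
})
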