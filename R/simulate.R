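# Forward model of the SSFM instrument: labeled tissue phantoms and the
# spectral cubes they would produce, with the statistical structure the
# pipeline assumes. This is the fixture generator for the whole test suite.

#' Default tissue-class parameter table
#'
#' Spectral parameters of the five tissue classes distinguished by Rd6G
#' spectral-shift imaging. Centers are the characteristic peak emission
#' wavelengths (melanoma 550, BCC 555, SCC 563, normal 570, nevus 581 nm);
#' spreads are the per-class scatter of per-pixel peak wavelengths
#' (2, 4, 3.3, 4.1 and 14.8 nm); band limits are the classification
#' intervals of [default_bands()]; typical concentrations are
#' 2, 8, 10, 16 and 12 uM. The nevus emission is driven by melanin
#' autofluorescence rather than Rd6G density, so its center is assigned
#' directly and deliberately sits outside the calibration span.
#'
#' @return A data.frame with columns `label`, `center_nm`, `spread_nm`,
#'   `band_lo_nm`, `band_hi_nm`, `typ_conc_uM`, `lineshape_sigma_nm`.
#' @export
default_class_table <- function() {
  tab <- data.frame(
    label = c("melanoma", "bcc", "scc", "normal", "nevus"),
    center_nm = c(550, 555, 563, SSFM_NORMAL_CENTER_NM, 581),
    spread_nm = c(2, 4, 3.3, 4.1, 14.8),
    band_lo_nm = c(548, 553, 559, 566, 575.5),
    band_hi_nm = c(553, 559, 566, 575.5, 588),
    typ_conc_uM = c(2, 8, 10, 16, 12),
    lineshape_sigma_nm = 6,
    stringsAsFactors = FALSE)
  validate_class_table(tab)
  tab
}

validate_class_table <- function(tab) {
  need <- c("label", "center_nm", "spread_nm", "band_lo_nm", "band_hi_nm",
            "typ_conc_uM", "lineshape_sigma_nm")
  if (!all(need %in% names(tab)))
    stop_config(sprintf("class table must have columns %s",
                        paste(need, collapse = ", ")))
  with(tab, {
    if (any(!(band_lo_nm < center_nm & center_nm < band_hi_nm)))
      stop_config("class table: band_lo < center < band_hi violated")
    if (any(spread_nm < 0)) stop_config("class table: spread must be >= 0")
    if (any(typ_conc_uM <= 0)) stop_config("class table: typ_conc must be > 0")
  })
  invisible(tab)
}

#' Noise model of the detector
#'
#' @param kind `"none"`, `"gaussian"` (additive) or `"rician"` (magnitude of
#'   a complex Gaussian perturbation, the appropriate model for magnitude
#'   spectra).
#' @param sigma Noise scale, in a.u., or as a fraction of the per-pixel
#'   peak amplitude when `relative = TRUE`.
#' @param relative Interpret `sigma` relative to each pixel's noise-free
#'   peak amplitude ("percent of amplitude" study conditions).
#' @return A `noise_model` list.
#' @export
noise_model <- function(kind = c("none", "gaussian", "rician"), sigma = 0,
                        relative = FALSE) {
  kind <- match.arg(kind)
  if (sigma < 0) stop_config("noise sigma must be >= 0")
  structure(list(kind = kind, sigma = sigma, relative = isTRUE(relative)),
            class = "noise_model")
}

#' Fluorescence intensity versus fluorophore concentration
#'
#' Quenched linear model \eqn{I(c) = a\,c\,e^{-c/\kappa}}: intensity grows
#' with fluorophore density until self-quenching/reabsorption turns it over
#' at \eqn{c=\kappa}, making intensity a two-valued-inverse function of
#' concentration. The default \eqn{\kappa = 30/\ln 4} uM places the
#' equal-intensity ambiguity pair exactly at 10 and 40 uM.
#'
#' @param conc_uM Concentration(s) in uM, >= 0.
#' @param amplitude Scale factor a (a.u.), > 0.
#' @param quench_uM Quench constant \eqn{\kappa} in uM, > 0.
#' @return Intensity in a.u., vectorized over `conc_uM`.
#' @examples
#' intensity_vs_concentration(10) == intensity_vs_concentration(40)
#' @export
intensity_vs_concentration <- function(conc_uM, amplitude = 1,
                                       quench_uM = default_quench_uM()) {
  if (any(conc_uM < 0)) stop_config("concentration must be >= 0")
  if (amplitude <= 0 || quench_uM <= 0)
    stop_config("amplitude and quench constant must be > 0")
  amplitude * conc_uM * exp(-conc_uM / quench_uM)
}

#' Peak emission wavelength versus concentration
#'
#' The redshift of the Rd6G emission peak with fluorophore density,
#' evaluated on the monotone calibration interpolant.
#'
#' @param conc_uM Concentration(s) in uM, within the calibration span
#'   unless `extrapolate`.
#' @param table A [calibration_table()].
#' @param extrapolate Allow evaluation outside the anchor span (linear
#'   continuation of the end slopes).
#' @return Wavelength(s) in nm, monotone non-decreasing in `conc_uM`.
#' @export
wavelength_vs_concentration <- function(conc_uM, table = default_calibration(),
                                        extrapolate = FALSE) {
  span <- range(table$anchors$conc_uM)
  out_of <- conc_uM < span[1] | conc_uM > span[2]
  if (any(out_of) && !extrapolate)
    stop_validation(sprintf(
      "concentration(s) %s outside the calibration span [%g, %g] uM",
      paste(signif(conc_uM[out_of], 6), collapse = ", "), span[1], span[2]))
  eval_calibration_forward(table, conc_uM)
}

# --- phantoms -------------------------------------------------------------

#' Phantom specification
#'
#' A labeled rectangular tissue phantom standing in for a stained specimen.
#' Regions are painted over the background in list order; later regions
#' overwrite earlier ones. R-side rectangles use inclusive 1-based bounds
#' `i0:i1` x `j0:j1`; the JSON/YAML dialect of [phantom_spec_from_file()]
#' uses 0-based half-open `[x0,x1) x [y0,y1)` rectangles instead.
#'
#' @param m,n Scan size in pixels (rows, columns); defaults 60 x 30, the
#'   instrument's standard 1800-pixel scan.
#' @param pixel_um Pixel size (um).
#' @param background Background class label.
#' @param regions List of `list(i0, i1, j0, j1, label)` rectangles.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(m = 60, n = 30, pixel_um = 16,
                         background = "normal", regions = list()) {
  if (m < 1 || n < 1) stop_config("phantom grid must be at least 1 x 1")
  for (r in regions) {
    if (!all(c("i0", "i1", "j0", "j1", "label") %in% names(r)))
      stop_config("each region needs i0, i1, j0, j1, label")
    if (r$i0 < 1 || r$j0 < 1 || r$i1 > m || r$j1 > n ||
        r$i0 > r$i1 || r$j0 > r$j1)
      stop_config(sprintf("region '%s' [%d:%d, %d:%d] outside the %d x %d grid",
                          r$label, r$i0, r$i1, r$j0, r$j1, m, n))
  }
  structure(list(m = m, n = n, pixel_um = pixel_um,
                 background = background, regions = regions),
            class = "phantom_spec")
}

#' Read a phantom specification from JSON or YAML
#'
#' File dialect: `{m, n, pixel_um, background, regions: [{x0, y0, x1, y1,
#' label}, ...]}` with 0-based half-open pixel rectangles
#' `[x0,x1) x [y0,y1)` (x indexes rows, y columns).
#'
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) file.
#' @return A [phantom_spec()].
#' @export
phantom_spec_from_file <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  regions <- lapply(obj$regions %||% list(), function(r)
    list(i0 = r$x0 + 1L, i1 = r$x1, j0 = r$y0 + 1L, j1 = r$y1,
         label = r$label))
  phantom_spec(m = obj$m %||% 60, n = obj$n %||% 30,
               pixel_um = obj$pixel_um %||% 16,
               background = obj$background %||% "normal",
               regions = regions)
}

#' Paint a phantom into a label map
#'
#' @param spec A [phantom_spec()].
#' @return Character m x n matrix of class labels.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  labels <- matrix(spec$background, spec$m, spec$n)
  for (r in spec$regions)
    labels[r$i0:r$i1, r$j0:r$j1] <- r$label
  labels
}

# --- cube synthesis -------------------------------------------------------

#' Simulate a spectral cube from a labeled phantom
#'
#' Forward model of one raster scan. Per pixel: a true peak wavelength
#' \eqn{\lambda^*} is drawn from the class distribution
#' (Uniform(center +/- spread/2) by default, so the recovered full range of
#' a class equals its spread; Gaussian with sd = spread/4 behind
#' `spread_dist = "gaussian"`); the true concentration is the class's
#' typical value; the emission lineshape is
#' \eqn{A\,\exp(-(\lambda-\lambda^*)^2 / 2\sigma_{line}^2)} with amplitude
#' from [intensity_vs_concentration()]; detector noise is added (additive
#' Gaussian, or Rician as the magnitude of a complex Gaussian
#' perturbation); the response at and below the dichroic cutoff is zeroed.
#'
#' Randomness comes from R's default Mersenne-Twister generator seeded with
#' `seed`; draw order (all peak wavelengths first, then the noise matrix)
#' is part of the contract, so equal seeds give identical cubes.
#'
#' @param labels Character m x n label matrix (see [make_phantom()]).
#' @param classes Class table, see [default_class_table()].
#' @param grid [wavelength_grid()]; must cover the 540--600 nm Rd6G
#'   emission region.
#' @param noise A [noise_model()].
#' @param seed Integer RNG seed.
#' @param amplitude Intensity scale a of the concentration model (a.u.).
#' @param quench_uM Quench constant (uM).
#' @param dichroic_cutoff_nm Wavelengths <= this are zeroed (default 535).
#' @param spread_dist `"uniform"` or `"gaussian"` per-pixel peak-wavelength
#'   distribution.
#' @param pixel_um Pixel size recorded in the cube (um).
#' @param laser_nm Laser line recorded in the cube (nm).
#' @return List with `cube` (a [spectral_cube()]) and `truth` (a
#'   [pixel_maps()] holding the per-pixel true wavelength, amplitude and
#'   concentration).
#' @export
simulate_cube <- function(labels, classes = default_class_table(),
                          grid = default_grid(),
                          noise = noise_model("none"), seed = 1,
                          amplitude = 1, quench_uM = default_quench_uM(),
                          dichroic_cutoff_nm = SSFM_DICHROIC_CUTOFF_NM,
                          spread_dist = c("uniform", "gaussian"),
                          pixel_um = 16, laser_nm = SSFM_LASER_NM) {
  spread_dist <- match.arg(spread_dist)
  validate_class_table(classes)
  if (min(grid$values) > 540 || max(grid$values) < 600)
    stop_config("grid must cover the 540-600 nm Rd6G emission region")
  labs <- as.vector(labels)
  unknown <- setdiff(unique(labs), classes$label)
  if (length(unknown))
    stop_config(sprintf("label(s) not in the class table: %s",
                        paste(unknown, collapse = ", ")))
  m <- nrow(labels); n <- ncol(labels); P <- m * n
  idx <- match(labs, classes$label)
  center <- classes$center_nm[idx]
  spread <- classes$spread_nm[idx]
  conc <- classes$typ_conc_uM[idx]
  sig_line <- classes$lineshape_sigma_nm[idx]

  set.seed(as.integer(seed))
  lam_star <- if (spread_dist == "uniform")
    center + spread * (runif(P) - 0.5)
  else
    rnorm(P, mean = center, sd = spread / 4)
  amp <- intensity_vs_concentration(conc, amplitude, quench_uM)

  wl <- grid$values
  W <- length(wl)
  # W x P noise-free signal (vectors recycle column-major: `each = W`
  # makes a per-pixel constant down each column)
  S <- rep(amp, each = W) *
    exp(-(outer(wl, lam_star, "-"))^2 / (2 * rep(sig_line, each = W)^2))
  dim(S) <- c(W, P)
  sig_px <- if (noise$relative) noise$sigma * amp else rep(noise$sigma, P)
  if (noise$kind == "gaussian" && noise$sigma > 0) {
    S <- S + rnorm(W * P) * rep(sig_px, each = W)
  } else if (noise$kind == "rician" && noise$sigma > 0) {
    re <- S + rnorm(W * P) * rep(sig_px, each = W)
    im <- rnorm(W * P) * rep(sig_px, each = W)
    S <- sqrt(re^2 + im^2)
  }
  S[wl <= dichroic_cutoff_nm, ] <- 0
  arr <- array(aperm(array(S, dim = c(W, m, n)), c(2, 3, 1)),
               dim = c(m, n, W))
  cube <- spectral_cube(arr, grid, pixel_um = pixel_um, laser_nm = laser_nm,
                        notes = sprintf("simulated (seed %d, noise %s)",
                                        as.integer(seed), noise$kind))
  truth <- pixel_maps(intensity = matrix(amp, m, n),
                      wavelength = matrix(lam_star, m, n),
                      concentration = matrix(conc, m, n),
                      laser_nm = laser_nm)
  list(cube = cube, truth = truth)
}
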