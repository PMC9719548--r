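# False-color micrograph rendering.

#' Color ramp
#'
#' Ordered RGB stops over a map-unit domain, linearly interpolated per
#' channel. Out-of-range values are clamped to the end stops
#' (`policy = "clamp"`) or rendered as the missing color
#' (`policy = "missing-color"`, black).
#'
#' @param domain `c(lo, hi)` in map units, `lo < hi`.
#' @param stops Data.frame with columns `frac` (strictly increasing from 0
#'   to 1) and `r`, `g`, `b` (0--255).
#' @param policy `"clamp"` or `"missing-color"`.
#' @return An object of class `color_ramp`.
#' @export
color_ramp <- function(domain, stops, policy = c("clamp", "missing-color")) {
  policy <- match.arg(policy)
  stops <- as.data.frame(stops)
  if (!all(c("frac", "r", "g", "b") %in% names(stops)))
    stop_config("ramp stops need columns frac, r, g, b")
  if (domain[1] >= domain[2]) stop_config("ramp domain needs lo < hi")
  if (stops$frac[1] != 0 || stops$frac[nrow(stops)] != 1 ||
      any(diff(stops$frac) <= 0))
    stop_config("stop fractions must increase strictly from 0 to 1")
  if (any(stops[c("r", "g", "b")] < 0) || any(stops[c("r", "g", "b")] > 255))
    stop_config("RGB stop values must lie in 0..255")
  structure(list(domain = domain, stops = stops, policy = policy),
            class = "color_ramp")
}

#' Default spectral ramp for the 548--588 nm window
#'
#' A five-stop blue-to-dark-red ramp anchored at the class centers with
#' their verbal color assignments: melanoma-blue near 550 nm, BCC-green
#' near 555 nm, SCC-yellow/orange near 563 nm, vivid red for normal tissue
#' near 570 nm and dark red for nevus toward 588 nm. Linear in wavelength
#' (sequential order), not perceptually uniform. The original instrument's
#' exact per-bin RGB table is not published; this documented ramp is the
#' package default and can be replaced via [ramp_from_file()].
#'
#' @return A [color_ramp()] over \[548, 588\] nm.
#' @export
default_spectral_ramp <- function() {
  wl <- c(548, 555, 563, 570, 588)
  color_ramp(domain = c(548, 588),
             stops = data.frame(
               frac = (wl - 548) / (588 - 548),
               r = c(0, 0, 255, 255, 100),
               g = c(0, 200, 165, 0, 0),
               b = c(255, 0, 0, 0, 0)))
}

#' Read a color ramp from JSON
#'
#' Dialect: `{"domain": [548, 588], "stops": [{"frac": 0, "rgb":
#' [0,0,255]}, ...]}`.
#'
#' @param path JSON file path.
#' @return A [color_ramp()].
#' @export
ramp_from_file <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  obj <- jsonlite::fromJSON(path)
  rgb <- do.call(rbind, obj$stops$rgb)
  color_ramp(domain = obj$domain,
             stops = data.frame(frac = obj$stops$frac,
                                r = rgb[, 1], g = rgb[, 2], b = rgb[, 3]))
}

#' Map wavelengths to RGB through a ramp
#'
#' Linear interpolation per channel between the bracketing stops; `NA`
#' yields `NA` rows (callers render them black).
#'
#' @param lambda_nm Wavelength(s) in map units of the ramp domain.
#' @param ramp A [color_ramp()].
#' @return Numeric matrix, one row per input, columns `r`, `g`, `b`
#'   (0--255).
#' @export
wavelength_to_rgb <- function(lambda_nm, ramp = default_spectral_ramp()) {
  f <- (lambda_nm - ramp$domain[1]) / diff(ramp$domain)
  if (ramp$policy == "clamp") f <- pmin(pmax(f, 0), 1)
  else f[f < 0 | f > 1] <- NA_real_
  out <- sapply(c("r", "g", "b"), function(ch)
    approx(ramp$stops$frac, ramp$stops[[ch]], xout = f, rule = 2)$y)
  out <- matrix(out, ncol = 3, dimnames = list(NULL, c("r", "g", "b")))
  out[is.na(f), ] <- NA_real_
  out
}

#' Render a false-color micrograph
#'
#' Pure per-pixel rendering of one of the four SSFM image modes:
#' * `"intensity"` — grayscale over \[0, max(I)\];
#' * `"shift"` — the spectral ramp applied to the wavelength map (the
#'   spectral-shift micrograph);
#' * `"concentration"` — concentrations are first mapped back to their
#'   anchor wavelengths through the calibration, then sent through the same
#'   spectral ramp, so the concentration micrograph copies the spectral
#'   features of the shift micrograph;
#' * `"labels"` — flat class colors (each class rendered at its band
#'   midpoint through the ramp; unclassified mid-gray).
#'
#' Missing pixels render black. Each scan pixel becomes an
#' `upscale x upscale` block.
#'
#' @param maps A [pixel_maps()] (modes intensity/shift/concentration).
#' @param mode One of `"intensity"`, `"shift"`, `"concentration"`,
#'   `"labels"`.
#' @param labels Label matrix (required for `mode = "labels"`).
#' @param ramp A [color_ramp()].
#' @param calibration A [calibration_table()] used by the concentration
#'   mode.
#' @param bands A [class_bands()] used by the labels mode.
#' @param upscale Positive integer pixel-block size.
#' @return Numeric `(m*upscale) x (n*upscale) x 3` array in \[0, 1\]
#'   (8-bit quantized), ready for [write_image()].
#' @export
render_map <- function(maps = NULL,
                       mode = c("intensity", "shift", "concentration", "labels"),
                       labels = NULL, ramp = default_spectral_ramp(),
                       calibration = default_calibration(),
                       bands = default_bands(), upscale = 1) {
  mode <- match.arg(mode)
  upscale <- as.integer(upscale)
  if (upscale < 1) stop_config("upscale must be a positive integer")
  if (mode == "labels") {
    if (is.null(labels)) stop_validation("labels mode requires a label map")
    d <- dim(labels)
    mid <- setNames((bands$lo_nm + bands$hi_nm) / 2, bands$label)
    rgb <- matrix(NA_real_, length(labels), 3)
    known <- as.vector(labels) %in% names(mid)
    if (any(known))
      rgb[known, ] <- wavelength_to_rgb(mid[as.vector(labels)[known]], ramp)
    rgb[as.vector(labels) == "unclassified", ] <- 128
  } else {
    if (is.null(maps)) stop_validation(sprintf("mode '%s' requires pixel maps", mode))
    src <- switch(mode,
                  intensity = maps$intensity,
                  shift = maps$wavelength,
                  concentration = maps$concentration)
    if (is.null(src))
      stop_validation(sprintf("map for mode '%s' is absent", mode))
    d <- dim(src)
    if (mode == "intensity") {
      top <- suppressWarnings(max(src, na.rm = TRUE))
      if (!is.finite(top) || top <= 0) top <- 1
      g <- 255 * pmin(pmax(as.vector(src) / top, 0), 1)
      rgb <- cbind(g, g, g)
    } else {
      lam <- as.vector(src)
      if (mode == "concentration") {
        ok <- !is.na(lam)
        lam2 <- rep(NA_real_, length(lam))
        if (any(ok))
          lam2[ok] <- wavelength_vs_concentration(lam[ok], calibration,
                                                  extrapolate = TRUE)
        lam <- lam2
      }
      rgb <- wavelength_to_rgb(lam, ramp)
    }
  }
  rgb[is.na(rgb)] <- 0                       # missing renders black
  rgb <- round(rgb) / 255                    # 8-bit quantization
  img <- array(0, dim = c(d[1], d[2], 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[, ch], d[1], d[2])
  if (upscale > 1) {
    up <- array(0, dim = c(d[1] * upscale, d[2] * upscale, 3))
    for (ch in 1:3)
      up[, , ch] <- img[, , ch][rep(seq_len(d[1]), each = upscale),
                                rep(seq_len(d[2]), each = upscale)]
    img <- up
  }
  img
}

#' Write a rendered image losslessly
#'
#' 8-bit RGB PNG or TIFF; a re-read is pixel-identical.
#'
#' @param img `h x w x 3` array in \[0, 1\] from [render_map()].
#' @param path Output path.
#' @param format `"png"` or `"tiff"`; guessed from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff" else "png"
  }
  format <- match.arg(format, c("png", "tiff"))
  img <- round(img * 255) / 255
  ok <- tryCatch({
    if (format == "png") png::writePNG(img, path)
    else tiff::writeTIFF(img, path, bits.per.sample = 8L)
    TRUE
  }, error = function(e) stop_io(sprintf("cannot write image %s: %s", path,
                                         conditionMessage(e))))
  invisible(path)
}

#' Read an image written by [write_image()]
#'
#' @param path PNG or TIFF path.
#' @return `h x w x 3` array in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
}
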