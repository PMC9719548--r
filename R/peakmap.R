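# Per-pixel peak detection and the intensity / wavelength / shift matrices.

#' Co-registered pixel maps
#'
#' Container for the three matrices the pipeline produces: signal intensity
#' \eqn{[I_{ij}]} (a.u.), peak emission wavelength \eqn{[\lambda_{ij}]}
#' (nm) and, after calibration, fluorophore concentration \eqn{[c_{ij}]}
#' (uM). Missing pixels (dead spectra, out-of-span calibration) are `NA`
#' throughout; renders show them black.
#'
#' @param intensity,wavelength Numeric m x n matrices.
#' @param concentration Optional m x n matrix (uM); `NULL` before
#'   calibration.
#' @param laser_nm Laser line (nm) the shift maps refer to.
#' @param missing_report Optional data.frame of pixels dropped by peak
#'   detection (`i`, `j`, `reason`).
#' @return An object of class `pixel_maps`.
#' @export
pixel_maps <- function(intensity, wavelength, concentration = NULL,
                       laser_nm = SSFM_LASER_NM, missing_report = NULL) {
  if (!identical(dim(intensity), dim(wavelength)))
    stop_validation("intensity and wavelength maps must share one shape")
  if (!is.null(concentration) && !identical(dim(concentration), dim(wavelength)))
    stop_validation("concentration map must share the maps' shape")
  structure(list(intensity = intensity, wavelength = wavelength,
                 concentration = concentration, laser_nm = laser_nm,
                 missing_report = missing_report),
            class = "pixel_maps")
}

#' @export
print.pixel_maps <- function(x, ...) {
  d <- dim(x$wavelength)
  cat(sprintf("<pixel_maps> %d x %d, %d missing, lambda %.6g-%.6g nm%s\n",
              d[1], d[2], sum(is.na(x$wavelength)),
              suppressWarnings(min(x$wavelength, na.rm = TRUE)),
              suppressWarnings(max(x$wavelength, na.rm = TRUE)),
              if (is.null(x$concentration)) "" else ", calibrated"))
  invisible(x)
}

# vectorized detection over a W x P matrix; returns list(lambda, intensity,
# index, refined) with NA for empty pixels
detect_peak_matrix <- function(M, wl) {
  W <- nrow(M); P <- ncol(M)
  nz <- colSums(M > 0)
  k <- max.col(t(M), ties.method = "first")   # lowest-wavelength tie-break
  lambda <- wl[k]
  inten <- M[cbind(k, seq_len(P))]
  refined <- rep(FALSE, P)
  interior <- k > 1L & k < W
  cand <- which(interior & nz >= 3L)
  if (length(cand)) {
    y1 <- M[cbind(k[cand] - 1L, cand)]
    y2 <- inten[cand]
    y3 <- M[cbind(k[cand] + 1L, cand)]
    pos <- y1 > 0 & y2 > 0 & y3 > 0
    l1 <- log(pmax(y1, .Machine$double.xmin))
    l2 <- log(pmax(y2, .Machine$double.xmin))
    l3 <- log(pmax(y3, .Machine$double.xmin))
    denom <- l1 - 2 * l2 + l3
    ok <- pos & denom < 0                       # concave parabola only
    idx <- cand[ok]
    if (length(idx)) {
      delta <- 0.5 * (l1[ok] - l3[ok]) / denom[ok]
      halfstep <- (wl[k[idx] + 1L] - wl[k[idx] - 1L]) / 2
      lambda[idx] <- wl[k[idx]] + delta * halfstep
      # parabola vertex value in log space = refined peak intensity
      vert <- l2[ok] - (l1[ok] - l3[ok])^2 / (8 * denom[ok])
      inten[idx] <- exp(vert)
      refined[idx] <- TRUE
    }
  }
  empty <- nz < 3L
  lambda[empty] <- NA_real_
  inten[empty] <- NA_real_
  list(lambda = lambda, intensity = inten, index = k, refined = refined,
       empty = empty)
}

#' Detect the fluorescence peak of one preprocessed spectrum
#'
#' The grid index is the global argmax over the unmasked band (ties go to
#' the lower wavelength, for determinism). The peak wavelength is refined
#' by a quadratic fit to the log-intensity at the argmax and its two
#' neighbours — exact for a Gaussian lineshape, since its log is exactly
#' quadratic — and falls back to the raw grid wavelength
#' (`refined = FALSE`) when the parabola is non-concave, a neighbour is
#' zero, or the argmax sits at a band edge.
#'
#' @param spec A preprocessed [spectrum()] with at least 3 nonzero samples.
#' @return A `peak_result`: list with `lambda_peak` (nm), `intensity_peak`
#'   (a.u.; the log-parabola vertex value when refined), `grid_index`
#'   (1-based argmax) and `refined` (logical).
#' @export
detect_peak <- function(spec) {
  if (!is_spectrum(spec)) stop_validation("`spec` must be a spectrum")
  if (sum(spec$intensity > 0) < 3)
    ssfm_stop("spectrum has fewer than 3 nonzero samples in the band",
              "ssfm_empty_signal_error")
  r <- detect_peak_matrix(matrix(spec$intensity), spec$grid$values)
  structure(list(lambda_peak = r$lambda[1], intensity_peak = r$intensity[1],
                 grid_index = r$index[1], refined = r$refined[1]),
            class = "peak_result")
}

#' Build the intensity and wavelength maps of a cube
#'
#' Runs the preprocessing chain on every pixel and detects each peak,
#' producing \eqn{[I_{ij}]} and \eqn{[\lambda_{ij}]}. Pixels whose spectra
#' are empty after masking are recorded as missing (`NA`), not zero, and
#' listed in the `missing_report`; the run aborts if more than
#' `missing_threshold` of the pixels are missing. Cubes failing
#' [validate_cube()] for any reason other than individual empty spectra are
#' rejected.
#'
#' @param cube A [spectral_cube()].
#' @param cfg A [preprocess_config()].
#' @param missing_threshold Maximum tolerated fraction of missing pixels
#'   (default 0.1).
#' @return A [pixel_maps()] (without concentration; see [apply_k()]).
#' @export
build_maps <- function(cube, cfg = preprocess_config(),
                       missing_threshold = 0.1) {
  if (!is_spectral_cube(cube)) stop_validation("`cube` must be a spectral_cube")
  rep0 <- validate_cube(cube)
  hard <- rep0$issues[rep0$issues$code != "empty_spectrum", , drop = FALSE]
  if (nrow(hard))
    stop_validation(sprintf("cube failed validation: %s at (%s,%s)",
                            hard$code[1], hard$i[1], hard$j[1]))
  d <- dim(cube$data)
  m <- d[1]; n <- d[2]; W <- d[3]
  M <- matrix(aperm(cube$data, c(3, 1, 2)), nrow = W)  # W x (m*n), i fastest
  M <- preprocess_matrix(M, cube$grid, cfg)
  r <- detect_peak_matrix(M, cube$grid$values)
  n_missing <- sum(r$empty)
  if (n_missing > missing_threshold * m * n)
    stop_validation(sprintf(
      "%d of %d pixels (%.1f%%) have no usable signal (threshold %.0f%%)",
      n_missing, m * n, 100 * n_missing / (m * n), 100 * missing_threshold))
  miss <- NULL
  if (n_missing) {
    ke <- which(r$empty)
    miss <- data.frame(i = (ke - 1L) %% m + 1L, j = (ke - 1L) %/% m + 1L,
                       reason = "empty_spectrum", stringsAsFactors = FALSE)
  }
  pixel_maps(intensity = matrix(r$intensity, m, n),
             wavelength = matrix(r$lambda, m, n),
             laser_nm = cube$laser_nm, missing_report = miss)
}

#' Spectral-shift map relative to the laser line
#'
#' \eqn{\Delta\lambda_{ij} = \lambda_{ij} - \lambda_L}. Missing pixels
#' propagate. Adding the laser line back reconstructs the wavelength map
#' exactly.
#'
#' @param maps A [pixel_maps()].
#' @param laser_nm Laser line (nm); defaults to the maps' own.
#' @return Numeric m x n matrix of shifts (nm).
#' @export
shift_map <- function(maps, laser_nm = NULL) {
  if (is.null(maps$wavelength)) stop_validation("wavelength map is absent")
  laser_nm <- laser_nm %||% maps$laser_nm
  maps$wavelength - laser_nm
}

#' Blue shift relative to normal tissue
#'
#' Returns `normal_reference_nm - lambda_map`, so a positive value is a
#' blue shift against healthy tissue. The reference defaults to the 569 nm
#' reporting convention under which the characteristic class blue shifts
#' are exactly 19 nm (melanoma), 14 nm (BCC) and 6 nm (SCC); the
#' classification center of normal tissue itself stays at 570 nm.
#'
#' @param maps A [pixel_maps()].
#' @param normal_reference_nm Reference wavelength (nm).
#' @return Numeric m x n matrix (nm; positive = blue-shifted vs normal).
#' @export
shift_vs_normal <- function(maps,
                            normal_reference_nm = SSFM_NORMAL_REFERENCE_NM) {
  if (is.null(maps$wavelength)) stop_validation("wavelength map is absent")
  normal_reference_nm - maps$wavelength
}
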