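# Wavelength grid and single-spectrum types.

#' Wavelength grid of the spectrometer
#'
#' A strictly increasing vector of wavelengths (nm) shared by every spectrum
#' of a cube. The spectrometer covers 200--1100 nm at a nominal 0.4 nm
#' resolution; grids outside that range are rejected.
#'
#' @param values Numeric vector of wavelengths in nm, strictly increasing,
#'   length >= 8, all within (200, 1100).
#' @param step Nominal spacing in nm; defaults to the median spacing of
#'   `values`.
#' @return An object of class `wavelength_grid` with elements `values` and
#'   `step`.
#' @examples
#' g <- wavelength_grid(seq(540, 600, by = 0.4))
#' length(g$values)
#' @export
wavelength_grid <- function(values, step = NULL) {
  values <- as.numeric(values)
  if (length(values) < 8)
    stop_validation("wavelength grid needs at least 8 samples")
  if (any(!is.finite(values)))
    stop_validation("wavelength grid contains non-finite values")
  d <- diff(values)
  if (any(d <= 0))
    stop_validation("wavelength grid must be strictly increasing")
  if (min(values) <= SSFM_SPECTROMETER_RANGE_NM[1] ||
      max(values) >= SSFM_SPECTROMETER_RANGE_NM[2])
    stop_validation(sprintf(
      "wavelength grid must lie within (%g, %g) nm",
      SSFM_SPECTROMETER_RANGE_NM[1], SSFM_SPECTROMETER_RANGE_NM[2]))
  if (is.null(step)) step <- median(d)
  if (step <= 0) stop_validation("grid step must be positive")
  structure(list(values = values, step = step), class = "wavelength_grid")
}

#' Default emission-region grid
#'
#' 500--650 nm at the instrument's 0.4 nm resolution (376 samples): the
#' spectrometer range restricted to the Rd6G emission region.
#'
#' @return A [wavelength_grid()].
#' @export
default_grid <- function() wavelength_grid(500 + 0.4 * (0:375), step = 0.4)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d samples, %.6g-%.6g nm, step %.3g nm\n",
              length(x$values), min(x$values), max(x$values), x$step))
  invisible(x)
}

is_wavelength_grid <- function(x) inherits(x, "wavelength_grid")

#' Single fluorescence spectrum
#'
#' One pixel's fluorescence spectrum on a shared wavelength grid. Negative
#' intensities (typical of baseline-subtracted data) are clipped to zero;
#' the number of clipped samples is kept in the `n_clipped` attribute.
#' Non-finite intensities are an error.
#'
#' @param grid A [wavelength_grid()].
#' @param intensity Numeric vector, same length as `grid$values`, in
#'   arbitrary units.
#' @return An object of class `spectrum` with elements `grid` and
#'   `intensity`.
#' @export
spectrum <- function(grid, intensity) {
  if (!is_wavelength_grid(grid)) stop_validation("`grid` must be a wavelength_grid")
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(grid$values))
    stop_validation("intensity length does not match the wavelength grid")
  if (any(!is.finite(intensity)))
    stop_validation("spectrum contains non-finite intensities")
  n_clip <- sum(intensity < 0)
  if (n_clip > 0) intensity <- pmax(intensity, 0)
  structure(list(grid = grid, intensity = intensity),
            n_clipped = n_clip, class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d samples, peak %.4g a.u. near %.6g nm\n",
              length(x$intensity), max(x$intensity),
              x$grid$values[which.max(x$intensity)]))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")
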