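# Spectral cube container and validation.

#' Spectral cube
#'
#' An m x n raster scan where every pixel carries one fluorescence spectrum
#' on a single shared wavelength grid (one spectrometer, one grid: per-pixel
#' grids are rejected upstream rather than resampled, since resampling would
#' silently move peak positions). Pixel (i, j) = (row, column), 1-based,
#' row-major raster order matching the stage's x-then-y scan.
#'
#' @param data Numeric m x n x W array of intensities (a.u.); W must equal
#'   the grid length. Negative values are clipped to zero (count kept in the
#'   `n_clipped` attribute).
#' @param grid A [wavelength_grid()] of length W.
#' @param pixel_um Pixel size in micrometers (default 16, the instrument's
#'   stage step).
#' @param laser_nm Excitation laser line in nm (default 532). Must lie below
#'   or within the grid coverage.
#' @param notes Optional character acquisition notes.
#' @return An object of class `spectral_cube`.
#' @seealso [validate_cube()], [read_cube()], [simulate_cube()]
#' @export
spectral_cube <- function(data, grid, pixel_um = 16,
                          laser_nm = SSFM_LASER_NM, notes = NULL) {
  if (!is_wavelength_grid(grid)) stop_validation("`grid` must be a wavelength_grid")
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_validation("`data` must be an m x n x W array")
  if (dim(data)[3] != length(grid$values))
    stop_validation("third dimension of `data` must equal the grid length")
  if (any(!is.finite(data)))
    stop_validation("cube contains non-finite intensities")
  if (laser_nm > max(grid$values))
    stop_validation("laser line lies above the grid coverage")
  n_clip <- sum(data < 0)
  if (n_clip > 0) data[data < 0] <- 0
  structure(list(data = data, grid = grid,
                 pixel_um = pixel_um, laser_nm = laser_nm, notes = notes),
            n_clipped = n_clip, class = "spectral_cube")
}

is_spectral_cube <- function(x) inherits(x, "spectral_cube")

cube_dim <- function(cube) dim(cube$data)[1:2]

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d pixels (%g um), %d wavelengths %.6g-%.6g nm, laser %g nm\n",
              d[1], d[2], x$pixel_um, d[3],
              min(x$grid$values), max(x$grid$values), x$laser_nm))
  invisible(x)
}

#' Extract one pixel's spectrum from a cube
#'
#' @param cube A [spectral_cube()].
#' @param i,j 1-based row / column pixel indices.
#' @return A [spectrum()].
#' @export
get_spectrum <- function(cube, i, j) {
  d <- dim(cube$data)
  if (i < 1 || i > d[1] || j < 1 || j > d[2])
    stop_validation(sprintf("pixel (%d,%d) outside the %d x %d scan", i, j, d[1], d[2]))
  spectrum(cube$grid, cube$data[i, j, ])
}

#' Validate a spectral cube
#'
#' Report-only check for the defects the pipeline cannot process: a
#' non-monotone wavelength grid (`grid_not_increasing`), non-finite
#' intensities (`non_finite`), negative intensities (`negative_intensity`;
#' normally already clipped on construction) and all-zero spectra
#' (`empty_spectrum`). Downstream stages require `ok = TRUE`.
#'
#' @param cube A [spectral_cube()] (or a structurally similar list, so that
#'   damaged objects can still be diagnosed).
#' @return A `ssfm_validation_report`: list with `ok` (logical) and `issues`
#'   (data.frame with columns `i`, `j`, `code`, `message`; grid-level issues
#'   carry `i = j = NA`). `ok` is `TRUE` iff `issues` has no rows.
#' @export
validate_cube <- function(cube) {
  issues <- list()
  add <- function(i, j, code, msg)
    issues[[length(issues) + 1L]] <<- data.frame(
      i = i, j = j, code = code, message = msg, stringsAsFactors = FALSE)
  gv <- cube$grid$values
  if (any(diff(gv) <= 0))
    add(NA_integer_, NA_integer_, "grid_not_increasing",
        "wavelength grid is not strictly increasing")
  d <- dim(cube$data)
  # per-pixel scans, vectorized over the wavelength axis
  flat <- matrix(cube$data, nrow = d[1] * d[2])  # pixels x W (column-major i fastest)
  bad_fin <- which(rowSums(!is.finite(flat)) > 0)
  bad_neg <- which(rowSums(flat < 0, na.rm = TRUE) > 0)
  bad_zero <- which(apply(abs(flat), 1, max) == 0)
  px <- function(k) c((k - 1L) %% d[1] + 1L, (k - 1L) %/% d[1] + 1L)
  for (k in bad_fin) { p <- px(k); add(p[1], p[2], "non_finite", "non-finite intensity") }
  for (k in setdiff(bad_neg, bad_fin)) { p <- px(k); add(p[1], p[2], "negative_intensity", "negative intensity") }
  for (k in bad_zero) { p <- px(k); add(p[1], p[2], "empty_spectrum", "spectrum is all zeros") }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(i = integer(), j = integer(), code = character(),
               message = character(), stringsAsFactors = FALSE)
  structure(list(ok = nrow(issues) == 0L, issues = issues),
            class = "ssfm_validation_report")
}

#' @export
print.ssfm_validation_report <- function(x, ...) {
  if (x$ok) cat("<validation> ok\n")
  else {
    cat(sprintf("<validation> %d issue(s)\n", nrow(x$issues)))
    print(utils::head(x$issues, 10))
  }
  invisible(x)
}

require_valid_cube <- function(cube) {
  rep <- validate_cube(cube)
  if (!rep$ok)
    stop_validation(sprintf("cube failed validation (%d issue(s); first: %s)",
                            nrow(rep$issues), rep$issues$code[1]),
                    report = rep)
  invisible(cube)
}
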