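# Cube and map readers/writers.
#
# Two cube dialects:
#  * "longcsv": header `i,j,wavelength_nm,intensity`, one row per
#    (pixel, wavelength) sample, i and j 1-based. Human-readable.
#  * "container": hierarchical JSON mirroring an HDF5-style layout with
#    datasets grid/wavelength_nm (length W), cube/intensity (m x n x W)
#    and attrs {laser_nm, pixel_um, created_by}.

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv", "txt")) "longcsv"
  else if (ext %in% c("json", "ssfm")) "container"
  else stop_io(sprintf("cannot guess cube format from extension '%s'", ext))
}

#' Read a spectral cube
#'
#' @param path Path to a cube file.
#' @param format `"longcsv"` or `"container"`; guessed from the file
#'   extension when omitted (`.csv` vs `.json`).
#' @param pixel_um,laser_nm Metadata defaults used by the long-CSV dialect,
#'   which does not carry them; ignored by the container dialect.
#' @return A [spectral_cube()]. The declared scan is the full
#'   `max(i) x max(j)` grid; a missing pixel is an error naming the absent
#'   (i, j) pairs, never a silent fill.
#' @export
read_cube <- function(path, format = NULL, pixel_um = 16,
                      laser_nm = SSFM_LASER_NM) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  format <- if (is.null(format)) guess_format(path) else
    match.arg(format, c("longcsv", "container"))
  if (format == "longcsv") read_cube_longcsv(path, pixel_um, laser_nm)
  else read_cube_container(path)
}

read_cube_longcsv <- function(path, pixel_um, laser_nm) {
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c("i", "j", "wavelength_nm", "intensity")
  if (!all(need %in% names(dt)))
    stop_io(sprintf("malformed long-CSV header: expected columns %s",
                    paste(need, collapse = ", ")))
  data.table::setorderv(dt, c("i", "j", "wavelength_nm"))
  m <- max(dt$i); n <- max(dt$j)
  if (min(dt$i) < 1 || min(dt$j) < 1)
    stop_io("long-CSV pixel indices must be 1-based positive integers")
  # shared grid: taken from the first pixel, all others must match exactly
  first <- dt[dt$i == dt$i[1] & dt$j == dt$j[1], ]
  wl <- first$wavelength_nm
  W <- length(wl)
  counts <- dt[, .N, by = c("i", "j")]
  if (any(counts$N != W))
    stop_validation("inconsistent wavelength vectors across pixels (grid mismatch)")
  present <- paste(counts$i, counts$j)
  declared <- as.vector(outer(seq_len(m), seq_len(n), paste))
  absent <- setdiff(declared, present)
  if (length(absent))
    stop_validation(sprintf("declared %d x %d scan is missing pixel(s): %s",
                            m, n, paste0("(", sub(" ", ",", absent), ")",
                                         collapse = " ")))
  wmat <- matrix(dt$wavelength_nm, nrow = W)
  if (any(abs(wmat - wl) > 1e-9))
    stop_validation("inconsistent wavelength vectors across pixels (grid mismatch)")
  arr <- array(NA_real_, dim = c(m, n, W))
  # dt is sorted by (i, j, wavelength): index arithmetic instead of a loop
  arr[cbind(rep(counts$i, each = W), rep(counts$j, each = W), rep(seq_len(W), m * n))] <-
    dt$intensity
  spectral_cube(arr, wavelength_grid(wl), pixel_um = pixel_um,
                laser_nm = laser_nm)
}

read_cube_container <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop_io(sprintf(
                    "malformed container file %s: %s", path, conditionMessage(e))))
  if (is.null(obj$grid$wavelength_nm) || is.null(obj$cube$intensity))
    stop_io("container file lacks grid/wavelength_nm or cube/intensity")
  arr <- obj$cube$intensity
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop_io("container cube/intensity is not an m x n x W array")
  attrs <- obj$attrs
  spectral_cube(arr, wavelength_grid(obj$grid$wavelength_nm),
                pixel_um = attrs$pixel_um %||% 16,
                laser_nm = attrs$laser_nm %||% SSFM_LASER_NM,
                notes = attrs$notes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectral cube
#'
#' The emitted file re-reads to an equal cube (values equal within
#' representation precision: full double precision in both dialects).
#'
#' @param cube A valid [spectral_cube()].
#' @param path Output path.
#' @param format `"longcsv"` or `"container"`; guessed from the extension
#'   when omitted.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = NULL) {
  if (!is_spectral_cube(cube)) stop_validation("`cube` must be a spectral_cube")
  format <- if (is.null(format)) guess_format(path) else
    match.arg(format, c("longcsv", "container"))
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop_io(sprintf("unwritable path: %s", path))
  d <- dim(cube$data)
  if (format == "longcsv") {
    W <- d[3]
    dt <- data.table::data.table(
      i = rep(rep(seq_len(d[1]), each = W), times = d[2]),
      j = rep(seq_len(d[2]), each = d[1] * W),
      wavelength_nm = rep(cube$grid$values, d[1] * d[2]),
      intensity = as.vector(aperm(cube$data, c(3, 1, 2))))
    data.table::setorderv(dt, c("i", "j", "wavelength_nm"))
    data.table::fwrite(dt, path)
  } else {
    obj <- list(
      grid = list(wavelength_nm = cube$grid$values),
      cube = list(intensity = cube$data),
      attrs = list(laser_nm = cube$laser_nm, pixel_um = cube$pixel_um,
                   created_by = paste0("ssfm ", as.character(packageVersion("ssfm"))),
                   notes = cube$notes))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

# --- map export -----------------------------------------------------------

#' Export a pixel map as long CSV
#'
#' Writes `i,j,value` rows (1-based, raster order). Missing pixels are kept
#' as literal `NA`.
#'
#' @param map Numeric m x n matrix (may contain `NA`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  d <- dim(map)
  dt <- data.table::data.table(
    i = rep(seq_len(d[1]), times = d[2]),
    j = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(map))
  data.table::setorderv(dt, c("i", "j"))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a pixel map written by [write_map_csv()]
#'
#' @param path CSV path with columns `i,j,value`.
#' @return Numeric matrix.
#' @export
read_map_csv <- function(path) {
  dt <- data.table::fread(path, showProgress = FALSE)
  if (!all(c("i", "j", "value") %in% names(dt)))
    stop_io("map CSV must have columns i,j,value")
  m <- max(dt$i); n <- max(dt$j)
  out <- matrix(NA_real_, m, n)
  out[cbind(dt$i, dt$j)] <- dt$value
  out
}

#' Export a pixel map as float32 TIFF
#'
#' TIFF float samples are stored normalized to \[0.1, 0.9\] over the map's
#' finite range (the underlying writer only defines storage inside \[0, 1\]);
#' the affine transform is recorded in a JSON sidecar `<path>.json` with
#' fields `lo` and `hi`, and missing pixels are encoded as 0. The round trip
#' through [read_map_tiff()] is exact to float32 precision.
#'
#' @param map Numeric m x n matrix, `NA` allowed.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  fin <- is.finite(map)
  lo <- if (any(fin)) min(map[fin]) else 0
  hi <- if (any(fin)) max(map[fin]) else 1
  if (hi <= lo) hi <- lo + 1
  norm <- 0.1 + 0.8 * (map - lo) / (hi - lo)
  norm[!fin] <- 0
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(lo = lo, hi = hi, missing_value = 0,
                            shape = dim(map)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pixel map written by [write_map_tiff()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must sit next to it).
#' @return Numeric matrix with `NA` for missing pixels.
#' @export
read_map_tiff <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop_io(sprintf("missing TIFF sidecar: %s", side))
  meta <- jsonlite::fromJSON(side)
  norm <- tiff::readTIFF(path)
  out <- meta$lo + (norm - 0.1) / 0.8 * (meta$hi - meta$lo)
  out[norm == 0] <- NA_real_
  out
}
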