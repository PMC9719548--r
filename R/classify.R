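# Spectral-band segmentation of the wavelength map and per-class summary
# statistics.

#' Classification bands
#'
#' Ordered, pairwise disjoint closed-open wavelength intervals `[lo, hi)`
#' per tissue label. Wavelengths outside every band classify as
#' `"unclassified"`; missing pixels stay `"missing"`.
#'
#' @param bands Data.frame with columns `label`, `lo_nm`, `hi_nm`.
#' @return An object of class `class_bands`.
#' @export
class_bands <- function(bands) {
  bands <- as.data.frame(bands)
  if (!all(c("label", "lo_nm", "hi_nm") %in% names(bands)))
    stop_config("bands need columns label, lo_nm, hi_nm")
  bands <- bands[order(bands$lo_nm), , drop = FALSE]
  if (any(bands$hi_nm <= bands$lo_nm))
    stop_config("each band needs lo < hi")
  if (nrow(bands) > 1 &&
      any(bands$lo_nm[-1] < bands$hi_nm[-nrow(bands)]))
    stop_config("bands must be pairwise disjoint")
  rownames(bands) <- NULL
  structure(bands, class = c("class_bands", "data.frame"))
}

#' Default classification bands
#'
#' melanoma \[548, 553), BCC \[553, 559), SCC \[559, 566), normal
#' \[566, 575.5), nevus \[575.5, 588) nm. Boundaries between class centers
#' are midpoints, consistent with the 553--565 nm nonmelanoma range; the
#' normal/nevus boundary at 575.5 nm splits the "longer than 575 nm" nevus
#' region from the 570 +/- 3 nm normal band. Together they cover
#' \[548, 588); everything else is unclassified. Fully overridable.
#'
#' @return A [class_bands()].
#' @export
default_bands <- function() {
  tab <- default_class_table()
  class_bands(data.frame(label = tab$label, lo_nm = tab$band_lo_nm,
                         hi_nm = tab$band_hi_nm, stringsAsFactors = FALSE))
}

classify_values <- function(lambda, bands) {
  out <- rep("unclassified", length(lambda))
  for (r in seq_len(nrow(bands)))
    out[!is.na(lambda) & lambda >= bands$lo_nm[r] & lambda < bands$hi_nm[r]] <-
      bands$label[r]
  out[is.na(lambda)] <- "missing"
  out
}

#' Classify the wavelength map into tissue classes
#'
#' Per-pixel closed-open interval lookup, optionally followed by a 3x3
#' modal (majority-vote) filter on the labels — the spatial counterpart of
#' the spectral smoothing — where ties keep the original label and missing
#' pixels stay missing.
#'
#' @param maps A [pixel_maps()] or a bare wavelength matrix.
#' @param bands A [class_bands()].
#' @param spatial_median Apply the 3x3 modal filter.
#' @return Character m x n label matrix (`"missing"` for missing pixels).
#' @export
classify_map <- function(maps, bands = default_bands(),
                         spatial_median = FALSE) {
  lam <- if (inherits(maps, "pixel_maps")) maps$wavelength else maps
  labels <- matrix(classify_values(as.vector(lam), bands),
                   nrow(lam), ncol(lam))
  if (spatial_median) labels <- modal_filter3(labels)
  labels
}

# 3x3 majority vote; ties keep the original label, missing stays missing
modal_filter3 <- function(labels) {
  m <- nrow(labels); n <- ncol(labels)
  out <- labels
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (labels[i, j] == "missing") next
    nb <- labels[max(1, i - 1):min(m, i + 1), max(1, j - 1):min(n, j + 1)]
    nb <- nb[nb != "missing"]
    tab <- table(nb)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) out[i, j] <- winners
  }
  out
}

# characteristic class shift: median shift rounded to the nearest nm.
# For the flat-topped per-pixel peak distributions the generator produces, a
# histogram arg-max over 1-nm bins has near-ties across adjacent bins and is
# unstable; median and mode coincide for unimodal symmetric distributions.
modal_shift_nm <- function(shift) {
  if (!length(shift) || all(is.na(shift))) return(NA_real_)
  round(median(shift, na.rm = TRUE))
}

#' Per-class summary statistics
#'
#' For every label of the class table (plus `"unclassified"`): pixel count,
#' fraction of non-missing pixels, mean/min/max recovered peak wavelength,
#' spectral width (max - min, the class's data-scattering statistic), modal
#' spectral shift vs the laser line (median shift rounded to the nearest
#' nm), and the class's typical concentration from the table lookup (so
#' nevus, which sits outside the calibration span, is still reportable).
#'
#' @param labels Character label matrix from [classify_map()].
#' @param maps A [pixel_maps()] co-registered with `labels`.
#' @param classes Class table for the concentration lookup.
#' @param laser_nm Laser line; defaults to the maps' own.
#' @return Data.frame with one row per label: `label`, `count`, `fraction`,
#'   `mean_nm`, `min_nm`, `max_nm`, `width_nm`, `modal_shift_nm`,
#'   `typ_conc_uM`. Empty classes keep `count = 0` and `NA` statistics.
#' @export
summarize_classes <- function(labels, maps, classes = default_class_table(),
                              laser_nm = NULL) {
  if (!identical(dim(labels), dim(maps$wavelength)))
    stop_validation("labels and wavelength map are not co-registered")
  laser_nm <- laser_nm %||% maps$laser_nm
  lam <- as.vector(maps$wavelength)
  lab <- as.vector(labels)
  keep <- lab != "missing"
  n_valid <- sum(keep)
  all_labels <- c(classes$label, "unclassified")
  rows <- lapply(all_labels, function(L) {
    x <- lam[keep & lab == L]
    cnt <- length(x)
    tc <- classes$typ_conc_uM[match(L, classes$label)]
    if (cnt == 0)
      return(data.frame(label = L, count = 0L, fraction = 0,
                        mean_nm = NA_real_, min_nm = NA_real_,
                        max_nm = NA_real_, width_nm = NA_real_,
                        modal_shift_nm = NA_real_, typ_conc_uM = tc,
                        stringsAsFactors = FALSE))
    data.frame(label = L, count = cnt, fraction = cnt / n_valid,
               mean_nm = mean(x), min_nm = min(x), max_nm = max(x),
               width_nm = max(x) - min(x),
               modal_shift_nm = modal_shift_nm(x - laser_nm),
               typ_conc_uM = tc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Long-format scatter table of all classified pixels
#'
#' One row per non-missing pixel, in raster order: pixel indices, label,
#' recovered peak wavelength, spectral shift vs the laser line and (when
#' calibrated) concentration. Suitable for the class-scatter plot.
#'
#' @param labels Label matrix from [classify_map()].
#' @param maps A [pixel_maps()].
#' @return Data.frame with columns `i`, `j`, `label`, `lambda_nm`,
#'   `shift_nm`, `conc_uM`.
#' @export
export_scatter <- function(labels, maps) {
  d <- dim(maps$wavelength)
  df <- data.frame(
    i = rep(seq_len(d[1]), times = d[2]),
    j = rep(seq_len(d[2]), each = d[1]),
    label = as.vector(labels),
    lambda_nm = as.vector(maps$wavelength),
    shift_nm = as.vector(maps$wavelength) - maps$laser_nm,
    conc_uM = if (is.null(maps$concentration)) NA_real_
              else as.vector(maps$concentration),
    stringsAsFactors = FALSE)
  df <- df[df$label != "missing", , drop = FALSE]
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}
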