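# Wavelength <-> concentration calibration: the characteristic operator
# linking the wavelength map to the concentration map. Identity (scalar) for
# bare fluorophore; a per-pixel nonlinear table lookup for stained tissue.

#' Calibration table
#'
#' Monotone anchor set linking Rd6G concentration to peak emission
#' wavelength, plus the parameters of the (non-monotone) intensity curve.
#' The forward curve \eqn{\lambda(c)} is a monotone piecewise-cubic
#' interpolant through the anchors ("monotone", the default) or piecewise
#' linear ("linear", kept for oracle cross-checks). The inverse
#' \eqn{c(\lambda)} is computed by root-finding on the forward interpolant,
#' so the round trip is exact to root-finder precision, not merely at the
#' anchors.
#'
#' @param anchors Data.frame or 2-column matrix of (conc_uM, wavelength_nm)
#'   pairs, strictly increasing in both coordinates, at least 2 rows.
#' @param amplitude,quench_uM Parameters of
#'   [intensity_vs_concentration()].
#' @param interpolation `"monotone"` or `"linear"`.
#' @return An object of class `calibration_table`.
#' @export
calibration_table <- function(anchors,
                              amplitude = 1,
                              quench_uM = default_quench_uM(),
                              interpolation = c("monotone", "linear")) {
  interpolation <- match.arg(interpolation)
  anchors <- as.data.frame(anchors)
  names(anchors) <- c("conc_uM", "wavelength_nm")
  if (nrow(anchors) < 2)
    stop_config("calibration table needs at least 2 anchors")
  if (any(diff(anchors$conc_uM) <= 0) || any(diff(anchors$wavelength_nm) <= 0))
    stop_config("calibration anchors must be strictly increasing in both coordinates")
  if (quench_uM <= 0 || amplitude <= 0)
    stop_config("amplitude and quench constant must be > 0")
  structure(list(anchors = anchors,
                 intensity_params = c(amplitude = amplitude,
                                      quench_uM = quench_uM),
                 interpolation = interpolation),
            class = "calibration_table")
}

#' Default calibration table
#'
#' Anchors at the documented class pairings (2, 550), (8, 555), (10, 563),
#' (16, 570) uM/nm. The nevus pairing (12 uM, 581 nm) is deliberately
#' excluded: nevus emission is dominated by melanin autofluorescence, not
#' Rd6G density, and would destroy the anchors' monotonicity. Intensity
#' parameters are a = 1, kappa = 30/ln 4.
#'
#' @return A [calibration_table()].
#' @export
default_calibration <- function() {
  calibration_table(data.frame(conc_uM = c(2, 8, 10, 16),
                               wavelength_nm = c(550, 555, 563, 570)))
}

#' Read a calibration table from JSON
#'
#' Dialect: `{"anchors": [[2, 550], ...], "amplitude": 1,
#' "kappa_uM": 21.6404, "interpolation": "monotone"}`.
#'
#' @param path JSON file path.
#' @return A [calibration_table()].
#' @export
calibration_from_file <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  obj <- jsonlite::fromJSON(path)
  calibration_table(as.data.frame(obj$anchors),
                    amplitude = obj$amplitude %||% 1,
                    quench_uM = obj$kappa_uM %||% default_quench_uM(),
                    interpolation = obj$interpolation %||% "monotone")
}

# forward interpolant lambda(c); extrapolates linearly with the end secants
eval_calibration_forward <- function(table, conc) {
  a <- table$anchors
  inside <- conc >= a$conc_uM[1] & conc <= a$conc_uM[nrow(a)]
  out <- numeric(length(conc))
  if (any(inside)) {
    out[inside] <- if (table$interpolation == "monotone")
      pracma::pchip(a$conc_uM, a$wavelength_nm, conc[inside])
    else
      approx(a$conc_uM, a$wavelength_nm, conc[inside])$y
  }
  if (any(!inside)) {
    k <- nrow(a)
    slo <- (a$wavelength_nm[2] - a$wavelength_nm[1]) /
      (a$conc_uM[2] - a$conc_uM[1])
    shi <- (a$wavelength_nm[k] - a$wavelength_nm[k - 1]) /
      (a$conc_uM[k] - a$conc_uM[k - 1])
    low <- !inside & conc < a$conc_uM[1]
    high <- !inside & !low
    out[low] <- a$wavelength_nm[1] + slo * (conc[low] - a$conc_uM[1])
    out[high] <- a$wavelength_nm[k] + shi * (conc[high] - a$conc_uM[k])
  }
  out
}

#' Invert the calibration: wavelength to concentration
#'
#' Inverse of the monotone \eqn{\lambda(c)} interpolant, exact at the
#' anchors, computed by bracketed root-finding on the forward curve (so
#' that `wavelength_to_concentration(wavelength_vs_concentration(c)) == c`
#' to high precision). Outside the anchor wavelength span the inverse uses
#' the linear end-slope continuation when `extrapolate = TRUE` and is a
#' range error otherwise.
#'
#' @param lambda_nm Wavelength(s), nm.
#' @param table A [calibration_table()].
#' @param extrapolate Allow wavelengths outside the anchor span.
#' @return Concentration(s), uM.
#' @export
wavelength_to_concentration <- function(lambda_nm,
                                        table = default_calibration(),
                                        extrapolate = FALSE) {
  a <- table$anchors
  k <- nrow(a)
  wlo <- a$wavelength_nm[1]; whi <- a$wavelength_nm[k]
  out_of <- lambda_nm < wlo | lambda_nm > whi
  if (any(out_of, na.rm = TRUE) && !extrapolate)
    stop_validation(sprintf(
      "wavelength(s) %s nm outside the calibration span [%g, %g] nm",
      paste(signif(lambda_nm[which(out_of)], 7), collapse = ", "), wlo, whi),
      lambda = lambda_nm[which(out_of)])
  vapply(lambda_nm, function(l) {
    if (is.na(l)) return(NA_real_)
    hit <- which(abs(a$wavelength_nm - l) < 1e-12)
    if (length(hit)) return(a$conc_uM[hit[1]])
    if (l < wlo) {
      slo <- (a$wavelength_nm[2] - a$wavelength_nm[1]) /
        (a$conc_uM[2] - a$conc_uM[1])
      return(a$conc_uM[1] + (l - wlo) / slo)
    }
    if (l > whi) {
      shi <- (a$wavelength_nm[k] - a$wavelength_nm[k - 1]) /
        (a$conc_uM[k] - a$conc_uM[k - 1])
      return(a$conc_uM[k] + (l - whi) / shi)
    }
    uniroot(function(c) eval_calibration_forward(table, c) - l,
            lower = a$conc_uM[1], upper = a$conc_uM[k],
            tol = 1e-12)$root
  }, numeric(1))
}

#' Characteristic calibration operator
#'
#' The operator that turns the wavelength map into the concentration map:
#' `"identity-scalar"` multiplies the wavelength map by a scalar k (the
#' bare-fluorophore simplification c = k lambda); `"table"` applies the
#' nonlinear monotone calibration per pixel (the diagonal, stained-tissue
#' case). A non-diagonal operator (spatial cross-talk between pixels) is
#' not supported: no construction for it is defined.
#'
#' @param kind `"identity-scalar"` or `"table"`.
#' @param k Scalar for the identity case.
#' @param table [calibration_table()] for the table case.
#' @return An object of class `k_operator`.
#' @export
k_operator <- function(kind = c("identity-scalar", "table"), k = 1,
                       table = NULL) {
  if (length(kind) == 1 && identical(kind, "non-diagonal"))
    ssfm_stop("non-diagonal calibration operators are unsupported",
              "ssfm_unsupported_error")
  kind <- match.arg(kind)
  if (kind == "table") {
    table <- table %||% default_calibration()
    if (!inherits(table, "calibration_table"))
      stop_config("`table` must be a calibration_table")
  }
  structure(list(kind = kind, k = k, table = table), class = "k_operator")
}

#' Apply the calibration operator to the wavelength map
#'
#' Fills the concentration map from the wavelength map: the concentration
#' micrograph depends only on the emission wavelength, never on the signal
#' intensity. With the table operator, pixels whose wavelength lies outside
#' the calibration span (e.g. nevus pixels dominated by melanin
#' autofluorescence) are set missing and counted in the
#' `out_of_span` attribute unless `extrapolate = TRUE`.
#'
#' @param maps A [pixel_maps()] with a wavelength map.
#' @param op A [k_operator()].
#' @param extrapolate Passed to [wavelength_to_concentration()] for the
#'   table case.
#' @return The [pixel_maps()] with `concentration` filled.
#' @export
apply_k <- function(maps, op = k_operator("table"), extrapolate = FALSE) {
  if (is.null(maps$wavelength)) stop_validation("wavelength map is absent")
  if (!inherits(op, "k_operator")) stop_config("`op` must be a k_operator")
  lam <- maps$wavelength
  if (op$kind == "identity-scalar") {
    conc <- op$k * lam
  } else {
    a <- op$table$anchors
    span <- range(a$wavelength_nm)
    vals <- as.vector(lam)
    oos <- !is.na(vals) & (vals < span[1] | vals > span[2])
    conc <- rep(NA_real_, length(vals))
    use <- !is.na(vals) & (extrapolate | !oos)
    if (any(use))
      conc[use] <- wavelength_to_concentration(vals[use], op$table,
                                               extrapolate = extrapolate)
    conc <- matrix(conc, nrow(lam), ncol(lam))
    attr(conc, "out_of_span") <- sum(oos & !extrapolate)
  }
  maps$concentration <- conc
  maps
}

#' Concentrations compatible with one signal intensity
#'
#' Inverts the quenched intensity curve \eqn{I(c) = a\,c\,e^{-c/\kappa}} at
#' a measured intensity: because the curve rises to a single maximum at
#' \eqn{c = \kappa} and falls beyond it, one intensity generally maps to
#' two candidate concentrations (one dilute, one dense), which is exactly
#' why intensity alone cannot map concentration while the emission
#' wavelength can. Roots are found by bracketed root-finding on each
#' monotone branch of \[0, `c_max`\].
#'
#' @param I Signal intensity, a.u., >= 0.
#' @param table A [calibration_table()] carrying the intensity parameters.
#' @param c_max Upper end of the search interval (uM).
#' @return Numeric vector of 0, 1 or 2 concentrations (uM); `0` when
#'   `I = 0`; empty when `I` exceeds the curve maximum.
#' @export
concentration_candidates_from_intensity <- function(I,
                                                    table = default_calibration(),
                                                    c_max = 200) {
  if (I < 0) stop_config("intensity must be >= 0")
  a <- table$intensity_params[["amplitude"]]
  kap <- table$intensity_params[["quench_uM"]]
  if (I == 0) return(0)
  Imax <- a * kap * exp(-1)
  if (I > Imax * (1 + 1e-12)) return(numeric(0))
  if (abs(I - Imax) <= Imax * 1e-12) return(kap)
  f <- function(c) intensity_vs_concentration(c, a, kap) - I
  roots <- uniroot(f, lower = 0, upper = kap, tol = 1e-13)$root
  if (kap < c_max && f(c_max) <= 0)
    roots <- c(roots, uniroot(f, lower = kap, upper = c_max, tol = 1e-13)$root)
  roots
}
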