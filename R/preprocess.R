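# Per-spectrum conditioning before peak detection. Stage order is fixed:
# laser-line masking -> Rician bias correction -> Gaussian smoothing.
# Masking first keeps smoothing from leaking laser energy into the emission
# band; debias must see raw magnitudes, not smoothed ones.

#' Preprocessing configuration
#'
#' @param dichroic_cutoff_nm Wavelengths at or below this are discarded
#'   (default 535 nm: the 532 nm laser line plus margin, so smoothing cannot
#'   leak laser energy into the emission band). Must be >= `laser_nm`.
#' @param smooth_sigma_nm Gaussian smoothing kernel sigma on the spectral
#'   axis, in nm (default 0.8, two grid steps; 0 disables).
#' @param rician_sigma Noise scale for Rician bias correction, in a.u.
#'   (0 disables).
#' @param laser_nm Excitation line, nm.
#' @param stages Stage order; only `c("mask", "debias", "smooth")` is valid —
#'   any other order is rejected, because reordering changes results.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(dichroic_cutoff_nm = SSFM_DICHROIC_CUTOFF_NM,
                              smooth_sigma_nm = 0.8, rician_sigma = 0,
                              laser_nm = SSFM_LASER_NM,
                              stages = c("mask", "debias", "smooth")) {
  if (dichroic_cutoff_nm < laser_nm)
    stop_config("dichroic cutoff must be at or above the laser wavelength")
  if (smooth_sigma_nm < 0) stop_config("smooth_sigma_nm must be >= 0")
  if (rician_sigma < 0) stop_config("rician_sigma must be >= 0")
  if (!identical(as.character(stages), c("mask", "debias", "smooth")))
    stop_config("preprocessing stage order is fixed: mask, debias, smooth")
  structure(list(dichroic_cutoff_nm = dichroic_cutoff_nm,
                 smooth_sigma_nm = smooth_sigma_nm,
                 rician_sigma = rician_sigma,
                 laser_nm = laser_nm, stages = stages),
            class = "preprocess_config")
}

# --- matrix kernels (W x P; columns are pixels) ----------------------------

mask_matrix <- function(M, wl, cutoff_nm) {
  if (cutoff_nm >= max(wl))
    ssfm_stop("dichroic cutoff at or above the whole grid leaves no signal",
              "ssfm_empty_signal_error")
  M[wl <= cutoff_nm, ] <- 0
  M
}

debias_matrix <- function(M, sigma) {
  if (sigma < 0) stop_config("rician sigma must be >= 0")
  if (sigma == 0) return(M)
  sqrt(pmax(M^2 - 2 * sigma^2, 0))
}

smooth_matrix <- function(M, step_nm, sigma_nm) {
  if (sigma_nm < 0) stop_config("smoothing sigma must be >= 0")
  if (sigma_nm == 0) return(M)
  sg <- sigma_nm / step_nm               # sigma in samples
  h <- ceiling(4 * sg)                   # kernel truncated at 4 sigma
  k <- dnorm(-h:h, sd = sg)
  k <- k / sum(k)                        # unit mass: total intensity conserved
  W <- nrow(M)
  if (W <= h) stop_validation("spectrum too short for the smoothing kernel")
  pad <- rbind(M[h:1, , drop = FALSE], M, M[W:(W - h + 1), , drop = FALSE])
  out <- stats::filter(pad, k, method = "convolution", sides = 2)
  out <- out[(h + 1):(h + W), , drop = FALSE]
  dimnames(out) <- NULL
  matrix(as.numeric(out), W)
}

# `grid` is a wavelength_grid: the nominal step (not a recomputed spacing)
# sizes the smoothing kernel, so spectrum- and cube-level paths agree exactly
preprocess_matrix <- function(M, grid, cfg) {
  M <- mask_matrix(M, grid$values, cfg$dichroic_cutoff_nm)
  M <- debias_matrix(M, cfg$rician_sigma)
  smooth_matrix(M, grid$step, cfg$smooth_sigma_nm)
}

# --- spectrum-level API -----------------------------------------------------

#' Mask the laser line / dichroic region
#'
#' Sets intensities at wavelengths `<= cutoff_nm` to zero, mimicking the
#' dichroic mirror that blocks the excitation beam; the grid is unchanged.
#'
#' @param spec A [spectrum()].
#' @param cutoff_nm Cutoff wavelength (nm). A cutoff at or above the whole
#'   grid is an error (no signal would remain).
#' @return The masked [spectrum()].
#' @export
mask_laser <- function(spec, cutoff_nm = SSFM_DICHROIC_CUTOFF_NM) {
  if (!is_spectrum(spec)) stop_validation("`spec` must be a spectrum")
  spectrum(spec$grid,
           mask_matrix(matrix(spec$intensity), spec$grid$values, cutoff_nm))
}

#' Rician bias correction
#'
#' For magnitude data with Rician noise of scale `sigma`, each sample M is
#' replaced by \eqn{\sqrt{\max(M^2 - 2\sigma^2, 0)}}, removing the noise
#' floor bias (the second moment of a Rice distribution is
#' \eqn{A^2 + 2\sigma^2}). `sigma = 0` is the identity.
#'
#' @param spec A [spectrum()].
#' @param sigma Noise scale, a.u., >= 0.
#' @return The debiased [spectrum()].
#' @export
rician_debias <- function(spec, sigma) {
  if (!is_spectrum(spec)) stop_validation("`spec` must be a spectrum")
  spectrum(spec$grid, debias_matrix(matrix(spec$intensity), sigma))
}

#' Gaussian smoothing along the spectral axis
#'
#' Discrete Gaussian convolution with the kernel sigma given in nm and
#' converted to grid samples; the kernel is truncated at 4 sigma,
#' normalized to unit mass, and the boundary is symmetric reflection.
#' Total integrated intensity is conserved for peaks away from the grid
#' edges, and the peak of a noise-free symmetric lineshape is not moved.
#'
#' @param spec A [spectrum()].
#' @param sigma_nm Kernel sigma in nm (0 = identity).
#' @return The smoothed [spectrum()].
#' @export
smooth_spectrum <- function(spec, sigma_nm) {
  if (!is_spectrum(spec)) stop_validation("`spec` must be a spectrum")
  spectrum(spec$grid, smooth_matrix(matrix(spec$intensity),
                                    spec$grid$step, sigma_nm))
}

#' Run the full preprocessing chain on one spectrum
#'
#' Applies, in fixed order: [mask_laser()], [rician_debias()],
#' [smooth_spectrum()].
#'
#' @param spec A [spectrum()].
#' @param cfg A [preprocess_config()].
#' @return The conditioned [spectrum()].
#' @export
preprocess_spectrum <- function(spec, cfg = preprocess_config()) {
  if (!is_spectrum(spec)) stop_validation("`spec` must be a spectrum")
  spectrum(spec$grid, preprocess_matrix(matrix(spec$intensity),
                                        spec$grid, cfg))
}
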