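# Shared fixtures: everything is generated in code, nothing is stored.

# Gaussian emission lineshape sampled on a grid
gaussian_spectrum <- function(center_nm, grid = default_grid(), amp = 1,
                              sigma_nm = 6) {
  spectrum(grid, amp * exp(-(grid$values - center_nm)^2 / (2 * sigma_nm^2)))
}

# tiny cube: every pixel a noise-free Gaussian lineshape at the given centers
tiny_cube <- function(centers, grid = wavelength_grid(seq(540, 600, by = 0.4)),
                      amp = 1, sigma_nm = 6) {
  m <- nrow(centers); n <- ncol(centers); W <- length(grid$values)
  arr <- array(0, dim = c(m, n, W))
  for (i in seq_len(m)) for (j in seq_len(n))
    arr[i, j, ] <- amp * exp(-(grid$values - centers[i, j])^2 / (2 * sigma_nm^2))
  spectral_cube(arr, grid)
}

# uniform single-class phantom scan at default 60 x 30 geometry
uniform_phantom <- function(label, m = 60, n = 30) matrix(label, m, n)

# class table with one class's spread (and optionally center) overridden
class_table_with <- function(label, spread_nm = NULL, center_nm = NULL) {
  tab <- default_class_table()
  k <- match(label, tab$label)
  if (!is.null(spread_nm)) tab$spread_nm[k] <- spread_nm
  if (!is.null(center_nm)) tab$center_nm[k] <- center_nm
  tab
}

# brute-force sub-grid peak oracle: densely evaluate the continuous
# lineshape model that generated the spectrum and take the argmax
dense_argmax_oracle <- function(center_nm, sigma_nm = 6,
                                lo = 540, hi = 600, step = 0.001) {
  lam <- seq(lo, hi, by = step)
  lam[which.max(exp(-(lam - center_nm)^2 / (2 * sigma_nm^2)))]
}
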