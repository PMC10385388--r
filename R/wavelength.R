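#' Wavelength grid of the spectrometer
#'
#' The instrument records reflectance in 125 contiguous bands spanning
#' 400--1000 nm (about 4.84 nm apart).  All spectra handled by this package
#' live on this grid.
#'
#' @param n_bands number of bands (default 125).
#' @param from,to first and last band centre in nm.
#' @return numeric vector of class `"wavelength_grid"`: strictly increasing,
#'   uniformly spaced band centres in nm.
#' @examples
#' g <- wavelength_grid()
#' length(g)    # 125
#' range(g)     # 400 1000
#' @export
wavelength_grid <- function(n_bands = 125L, from = 400, to = 1000) {
  if (n_bands < 2L) stop("wavelength_grid: need at least 2 bands")
  g <- seq(from, to, length.out = n_bands)
  structure(g, class = "wavelength_grid")
}

# Band column names used by the CSV dialect: centre rounded to 1 decimal.
band_column_names <- function(grid) sprintf("b%.1f", as.numeric(grid))

# Index of the band whose centre is closest to `nm`.
band_index <- function(grid, nm) which.min(abs(as.numeric(grid) - nm))

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("Wavelength grid: %d bands, %.1f-%.1f nm, spacing %.3f nm\n",
              length(x), min(x), max(x), diff(x)[1]))
  invisible(x)
}
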