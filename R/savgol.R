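#' Savitzky-Golay smoothing configuration
#'
#' @param window_length odd window size in bands, `3 <= window_length <= S`.
#' @param poly_order polynomial order, `0 <= poly_order < window_length`.
#' @return object of class `"smoothing_config"`.
#' @export
smoothing_config <- function(window_length = 11L, poly_order = 2L) {
  window_length <- as.integer(window_length)
  poly_order <- as.integer(poly_order)
  if (window_length < 3L || window_length %% 2L == 0L)
    stop("window_length must be an odd integer >= 3")
  if (poly_order < 0L || poly_order >= window_length)
    stop("poly_order must satisfy 0 <= poly_order < window_length")
  structure(list(window_length = window_length, poly_order = poly_order),
            class = "smoothing_config")
}

# Full n x n Savitzky-Golay smoothing matrix.  Interior points use the
# central row of the least-squares projection hat matrix of the symmetric
# window; the first and last half-windows reuse the fit over the first/last
# `window_length` points, evaluated off-centre, so the output has the input's
# length without fabricating data and the filter stays exact on polynomials
# of degree <= poly_order everywhere.
savgol_matrix <- function(n, cfg) {
  wl <- cfg$window_length
  p <- cfg$poly_order
  if (n < wl) stop("spectrum shorter than the smoothing window")
  h <- (wl - 1L) %/% 2L
  V <- outer(seq_len(wl) - (h + 1L), 0:p, `^`)     # centred offsets -h..h
  H <- V %*% solve(crossprod(V), t(V))             # wl x wl hat matrix
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i <= h) {
      A[i, 1:wl] <- H[i, ]
    } else if (i > n - h) {
      A[i, (n - wl + 1L):n] <- H[wl - (n - i), ]
    } else {
      A[i, (i - h):(i + h)] <- H[h + 1L, ]
    }
  }
  A
}

#' Savitzky-Golay smoothing of one spectrum
#'
#' Local least-squares polynomial smoothing: each band is replaced by the
#' value at that band of a degree-`poly_order` polynomial fitted to the
#' surrounding `window_length` bands.  Boundary bands are smoothed with the
#' asymmetric fit over the first/last full window.  The filter reproduces any
#' polynomial of degree `<= poly_order` exactly.
#'
#' @param spectrum numeric reflectance vector.
#' @param cfg a [smoothing_config()].
#' @param clip clip the result to `[0,1]` (reflectance is physically bounded);
#'   set `FALSE` to expose the raw linear filter.
#' @return smoothed vector of the same length.
#' @examples
#' savgol_smooth(c(0, 0, 1, 0, 0, 0, 0), smoothing_config(5, 2))
#' @export
savgol_smooth <- function(spectrum, cfg = smoothing_config(), clip = TRUE) {
  stopifnot(inherits(cfg, "smoothing_config"))
  y <- as.numeric(savgol_matrix(length(spectrum), cfg) %*% spectrum)
  if (clip) clip01(y) else y
}

#' Smooth every spectrum of a dataset
#'
#' Applies [savgol_smooth()] along the band axis of each record; labels,
#' phases, ids and grid are untouched.
#'
#' @param ds a [spectral_dataset()] with `M = 1`.
#' @param cfg a [smoothing_config()].
#' @param clip clip to `[0,1]` (default `TRUE`).
#' @return the smoothed `spectral_dataset`.
#' @export
smooth_dataset <- function(ds, cfg = smoothing_config(), clip = TRUE) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (n_samples(ds) == 0L) return(ds)
  x <- spectra_matrix(ds) %*% t(savgol_matrix(length(ds$grid), cfg))
  if (clip) x <- clip01(x)
  spectral_dataset(x, ds$labels, ds$year, ds$month, ds$ids, ds$grid)
}
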