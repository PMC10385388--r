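#' Spectral dataset container
#'
#' The central exchange object: a tensor of reflectance sequences of shape
#' `(N, S, M)` — `N` samples, `S` sequence steps (spectral bands), `M`
#' variables per step (`M = 1` for plain reflectance) — together with the
#' species label, acquisition phase (year, month) and identifier of every
#' sample, and the wavelength grid.
#'
#' @param data numeric array `(N, S, M)` or matrix `(N, S)` (taken as `M = 1`),
#'   values in `[0,1]`.
#' @param labels factor (or coercible) of species labels, length `N`.
#' @param year integer vector of acquisition years, length `N`.
#' @param month character/factor of acquisition months, length `N`.
#' @param ids character sample identifiers, length `N`.
#' @param grid a [wavelength_grid()] with `S` entries.
#' @return object of class `"spectral_dataset"`.
#' @export
spectral_dataset <- function(data, labels, year, month, ids = NULL,
                             grid = wavelength_grid(ncol(data))) {
  if (is.matrix(data)) data <- array(data, dim = c(nrow(data), ncol(data), 1L))
  if (length(dim(data)) != 3L) stop("data must be an (N, S, M) array")
  n <- dim(data)[1L]
  labels <- as.factor(labels)
  month <- factor(as.character(month), levels = c("June", "August"))
  year <- as.integer(year)
  if (length(labels) != n || length(year) != n || length(month) != n)
    stop("labels, year and month must each have one entry per sample")
  if (length(grid) != dim(data)[2L])
    stop("wavelength grid length must equal the number of sequence steps S")
  if (n > 0L && (min(data) < 0 || max(data) > 1))
    stop("reflectance values must lie in [0,1]")
  if (is.null(ids)) ids <- sprintf("s%06d", seq_len(n))
  structure(list(data = data, labels = labels, year = year, month = month,
                 ids = as.character(ids), grid = grid),
            class = "spectral_dataset")
}

#' Number of samples in a spectral dataset
#' @param ds a `spectral_dataset`.
#' @export
n_samples <- function(ds) dim(ds$data)[1L]

#' Reflectance matrix of a univariate dataset
#'
#' Drops the trailing `M = 1` axis and returns the `(N, S)` matrix.
#' @param ds a `spectral_dataset` with `M = 1`.
#' @export
spectra_matrix <- function(ds) {
  if (dim(ds$data)[3L] != 1L) stop("spectra_matrix is only defined for M = 1 datasets")
  matrix(ds$data, nrow = dim(ds$data)[1L], ncol = dim(ds$data)[2L])
}

# Phase key ("2020-June", ...) per sample.
dataset_phases <- function(ds) phase_key(ds$year, as.character(ds$month))

#' Subset a spectral dataset by sample index
#' @param x a `spectral_dataset`.
#' @param i integer or logical index over samples.
#' @param ... unused.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  spectral_dataset(x$data[i, , , drop = FALSE], droplevels(x$labels[i]),
                   x$year[i], x$month[i], x$ids[i], x$grid)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Spectral dataset: N = %d samples, S = %d bands, M = %d\n", d[1], d[2], d[3]))
  if (d[1] > 0) {
    cat("Species: ", paste(levels(x$labels), collapse = ", "), "\n", sep = "")
    tab <- table(x$labels, dataset_phases(x))
    print(tab)
  }
  invisible(x)
}

#' @export
summary.spectral_dataset <- function(object, ...) {
  d <- dim(object$data)
  cat(sprintf("Spectral dataset: N = %d, S = %d, M = %d, reflectance range [%.3f, %.3f]\n",
              d[1], d[2], d[3],
              if (d[1] > 0) min(object$data) else NA, if (d[1] > 0) max(object$data) else NA))
  invisible(table(object$labels, dataset_phases(object)))
}

#' Plot mean reflectance per species
#'
#' Draws the per-species mean spectrum (optionally for one phase), the
#' standard visual check that the simulated classes look like vegetation.
#'
#' @param x a `spectral_dataset` with `M = 1`.
#' @param phase optional phase key to restrict to (e.g. `"2020-June"`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.spectral_dataset <- function(x, phase = NULL, ...) {
  keep <- if (is.null(phase)) rep(TRUE, n_samples(x)) else dataset_phases(x) == phase
  xm <- spectra_matrix(x)[keep, , drop = FALSE]
  lab <- droplevels(x$labels[keep])
  mu <- t(vapply(levels(lab), function(l) colMeans(xm[lab == l, , drop = FALSE]),
                 numeric(ncol(xm))))
  graphics::matplot(as.numeric(x$grid), t(mu), type = "l", lty = 1,
                    xlab = "wavelength (nm)", ylab = "reflectance", ...)
  graphics::legend("topleft", legend = rownames(mu), col = seq_len(nrow(mu)),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(mu)
}
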