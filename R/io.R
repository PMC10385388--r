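#' Write a spectral dataset to CSV
#'
#' Column layout: `sample_id, species, year, month, b400.0, b404.8, ...,
#' b1000.0` — one band column per wavelength, named by the centre rounded to
#' one decimal.  UTF-8 with a header row.  Numbers are written with full
#' round-trip precision.
#'
#' @param ds a [spectral_dataset()] with `M = 1`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  x <- spectra_matrix(ds)
  colnames(x) <- band_column_names(ds$grid)
  df <- data.table::data.table(sample_id = ds$ids,
                               species = as.character(ds$labels),
                               year = ds$year,
                               month = as.character(ds$month))
  df <- cbind(df, data.table::as.data.table(x))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a spectral dataset from CSV
#'
#' Parses the dialect written by [write_dataset()] and validates it: the
#' header must carry all metadata and band columns, reflectance must lie in
#' `[0,1]`, and every species label must be one of `species_levels`.
#' Violations raise descriptive errors with the offending column name or row
#' number.
#'
#' @param path CSV file path.
#' @param grid expected [wavelength_grid()] (defines the band columns).
#' @param species_levels allowed species labels, in level order; defaults to
#'   the seven species of [default_archetypes()].  Pass `NULL` to accept any.
#' @return a [spectral_dataset()].
#' @export
read_dataset <- function(path, grid = wavelength_grid(),
                         species_levels = default_species_names()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("no records in ", path)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path)
  meta_cols <- c("sample_id", "species", "year", "month")
  missing_meta <- setdiff(meta_cols, names(df))
  if (length(missing_meta))
    stop("malformed header: missing column(s) ", paste(missing_meta, collapse = ", "))
  bands <- band_column_names(grid)
  missing_bands <- setdiff(bands, names(df))
  if (length(missing_bands))
    stop("missing band column(s): ", paste(head(missing_bands, 5L), collapse = ", "),
         if (length(missing_bands) > 5L) sprintf(" (and %d more)", length(missing_bands) - 5L) else "")
  x <- as.matrix(df[, bands])
  if (!is.numeric(x) || anyNA(x)) {
    bad <- which(apply(is.na(df[, bands]), 1L, any))[1L]
    stop("non-numeric or missing reflectance at row ", bad)
  }
  if (!is.null(species_levels)) {
    bad <- which(!df$species %in% species_levels)
    if (length(bad))
      stop(sprintf("unknown species label '%s' at row %d", df$species[bad[1L]], bad[1L]))
    labels <- factor(df$species, levels = species_levels)
  } else {
    labels <- factor(df$species)
  }
  badm <- which(!df$month %in% c("June", "August"))
  if (length(badm))
    stop(sprintf("unknown month '%s' at row %d", df$month[badm[1L]], badm[1L]))
  spectral_dataset(x, labels, df$year, df$month, df$sample_id, grid)
}

#' Species labels of the default archetypes
#' @return character vector of the seven species names.
#' @export
default_species_names <- function()
  vapply(default_archetypes(), function(a) a$species_name, "")
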