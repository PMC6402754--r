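#' Read canopy spectra from a wide table
#'
#' Reads a spectra table in the canonical wide layout: first column
#' \code{wavelength_nm}, one column per sample named
#' \code{S<season>_I<rate>_D<density>_R<rep>}. Two dialects are
#' supported: \code{wide_csv} (comma-separated text) and \code{xlsx}
#' (first sheet by default, same layout; \code{mapping} can rewrite
#' nonstandard headers before parsing, since deposited spreadsheets vary
#' in their column naming).
#'
#' @param path file to read
#' @param dialect \code{"wide_csv"} or \code{"xlsx"}
#' @param sheet sheet index or name for the xlsx dialect
#' @param mapping optional function applied to the raw data.frame before
#'   parsing (e.g. to rename columns of a nonstandard spreadsheet)
#' @return a \linkS4class{SpectralDataset} on the file's native grid
#' @export
readSpectra <- function(path, dialect = c("wide_csv", "xlsx"), sheet = 1,
                        mapping = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("spectra file not found: ", path)
  df <- switch(dialect,
    wide_csv = read.csv(path, check.names = FALSE),
    xlsx = as.data.frame(readxl::read_excel(path, sheet = sheet)))
  if (!is.null(mapping)) df <- mapping(df)
  if (!"wavelength_nm" %in% colnames(df))
    stop("missing wavelength column 'wavelength_nm' in ", path)
  wl <- df$wavelength_nm
  if (!is.numeric(wl) || any(!is.finite(wl)))
    stop("non-numeric wavelength values in column 'wavelength_nm'")
  steps <- diff(wl)
  if (length(wl) < 2 || any(abs(steps - steps[1]) > 1e-9))
    stop("wavelength axis is not a regular grid")
  grid <- WavelengthGrid(wl[1], wl[length(wl)], steps[1])
  samp <- colnames(df)[colnames(df) != "wavelength_nm"]
  if (!length(samp)) stop("no sample columns in ", path)
  if (anyDuplicated(samp))
    stop("duplicate sample key(s): ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "))
  for (s in samp)
    if (!is.numeric(df[[s]]))
      stop("non-numeric reflectance in column '", s, "'")
  m <- as.matrix(df[, samp, drop = FALSE])
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite reflectance at row %d, column '%s'",
                 bad[1], samp[bad[2]]))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative reflectance at %g nm in column '%s'",
                 wl[bad[1]], samp[bad[2]]))
  }
  SpectralDataset(unname(m), grid, parseSampleKey(samp))
}

#' Write canopy spectra as a wide CSV
#'
#' Deterministic layout: wavelengths ascending in the first column
#' \code{wavelength_nm}, sample columns ordered by sorted key string.
#' Values are written with 17 significant digits so that
#' \code{readSpectra(writeSpectra(x))} round-trips bit-identically.
#'
#' @param dataset a \linkS4class{SpectralDataset}
#' @param path output file
#' @param dialect only \code{"wide_csv"} is supported for writing
#' @return \code{path}, invisibly
#' @export
writeSpectra <- function(dataset, path, dialect = "wide_csv") {
  if (dialect != "wide_csv")
    stop("only the wide_csv dialect is supported for writing")
  m <- reflectance(dataset)
  ord <- order(colnames(m))
  out <- data.frame(wavelength_nm = wavelengths(dataset),
                    check.names = FALSE)
  for (j in ord) out[[colnames(m)[j]]] <- m[, j]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = ","), con)
  if (ncol(m) > 0) {
    body <- do.call(paste, c(lapply(out, function(v)
      formatC(v, digits = 17, format = "g")), sep = ","))
    writeLines(body, con)
  }
  invisible(path)
}

#' White-reference reflectance calibration
#'
#' Converts target and white-reference radiance scans to reflectance
#' fractions, band by band, as done against a barium-sulfate calibration
#' panel in the field.
#'
#' @param target radiance of the canopy scan
#' @param reference radiance of the white reference panel, > 0 everywhere
#' @param grid optional \linkS4class{WavelengthGrid} used to name the
#'   offending band in error messages
#' @return reflectance vector \code{target / reference}
#' @export
calibrateReflectance <- function(target, reference, grid = NULL) {
  if (length(target) != length(reference))
    stop("target and reference must have equal length")
  bad <- which(reference <= 0)
  if (length(bad)) {
    lab <- if (!is.null(grid)) paste0(wavelengths(grid)[bad[1]], " nm")
           else paste0("band ", bad[1])
    stop("reference radiance <= 0 at ", lab)
  }
  target / reference
}

#' Average replicate spectra
#'
#' Bandwise arithmetic mean of repeated scans of the same plot (the
#' field protocol averages six sequential readings per subplot).
#'
#' @param spectra list of reflectance vectors on a common grid, or a
#'   bands x scans matrix
#' @return the mean spectrum
#' @export
averageSpectra <- function(spectra) {
  if (is.list(spectra)) {
    if (!length(spectra)) stop("need at least one spectrum")
    n <- lengths(spectra)
    if (any(n != n[1])) stop("grid mismatch: spectra differ in length")
    spectra <- do.call(cbind, spectra)
  }
  rowMeans(spectra)
}

#' Resample a spectrum to a target grid
#'
#' Linear interpolation between neighbouring source bands; exact at
#' coincident wavelengths. Extrapolation outside the source support is
#' refused (instrument resampling only ever interpolates).
#'
#' @param values reflectance on the source grid
#' @param sourceGrid,targetGrid \linkS4class{WavelengthGrid} objects
#' @return reflectance on the target grid
#' @export
resampleToGrid <- function(values, sourceGrid, targetGrid) {
  swl <- wavelengths(sourceGrid)
  twl <- wavelengths(targetGrid)
  if (length(values) != length(swl))
    stop("values length differs from source grid")
  if (min(twl) < min(swl) || max(twl) > max(swl))
    stop(sprintf("extrapolation refused: target %g-%g nm outside source %g-%g nm",
                 min(twl), max(twl), min(swl), max(swl)))
  approx(swl, values, xout = twl, method = "linear")$y
}
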