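#' @include AllGenerics.R
NULL

#' WavelengthGrid: a regular wavelength axis
#'
#' Regular wavelength grid in nm. The canonical grid of field
#' spectroradiometer data used throughout the package is 350--2500 nm at a
#' 1 nm step (2151 bands), the grid to which instrument output is
#' resampled.
#'
#' @slot startNm first wavelength (nm)
#' @slot endNm last wavelength (nm)
#' @slot stepNm band spacing (nm), > 0
#' @export
setClass("WavelengthGrid",
  slots = c(startNm = "numeric", endNm = "numeric", stepNm = "numeric"))

setValidity("WavelengthGrid", function(object) {
  msg <- character()
  if (length(object@startNm) != 1 || length(object@endNm) != 1 ||
      length(object@stepNm) != 1)
    msg <- c(msg, "startNm, endNm and stepNm must be scalars")
  else {
    if (!(object@startNm < object@endNm))
      msg <- c(msg, "startNm must be < endNm")
    if (!(object@stepNm > 0))
      msg <- c(msg, "stepNm must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' @param startNm first wavelength (nm)
#' @param endNm last wavelength (nm)
#' @param stepNm band spacing (nm)
#' @return a \linkS4class{WavelengthGrid}
#' @examples
#' g <- WavelengthGrid()        # canonical 350-2500 nm, 1 nm
#' nBands(g)
#' @rdname WavelengthGrid-class
#' @export
WavelengthGrid <- function(startNm = 350, endNm = 2500, stepNm = 1) {
  new("WavelengthGrid", startNm = startNm, endNm = endNm, stepNm = stepNm)
}

#' @rdname wavelengths
setMethod("wavelengths", "WavelengthGrid", function(x)
  seq(x@startNm, x@endNm, by = x@stepNm))

#' @rdname nBands
setMethod("nBands", "WavelengthGrid", function(x)
  length(wavelengths(x)))

setMethod("show", "WavelengthGrid", function(object) {
  cat(sprintf("WavelengthGrid: %g-%g nm, step %g nm (%d bands)\n",
              object@startNm, object@endNm, object@stepNm, nBands(object)))
})

#' SpectralDataset: canopy reflectance spectra with treatment metadata
#'
#' A \linkS4class{SummarizedExperiment} holding one canopy reflectance
#' spectrum per experimental unit. Rows are wavelengths (rowData column
#' \code{wavelength_nm}), columns are plots; the single assay
#' \code{"reflectance"} holds reflectance fractions. \code{colData}
#' carries the treatment key: \code{season}, \code{irrigation} (fraction
#' of estimated crop evapotranspiration, e.g. 1.00 / 0.75 / 0.50),
#' \code{density} (seeds per square metre) and \code{replicate}. The
#' shared \linkS4class{WavelengthGrid} is stored in \code{metadata(x)$grid}.
#'
#' @export
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata SimpleList
setClass("SpectralDataset", contains = "SummarizedExperiment")

setValidity("SpectralDataset", function(object) {
  msg <- character()
  if (!"reflectance" %in% assayNames(object))
    msg <- c(msg, "assay 'reflectance' is required")
  if (!"wavelength_nm" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'wavelength_nm' is required")
  need <- c("season", "irrigation", "density", "replicate")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData misses: ", paste(miss, collapse = ", ")))
  g <- S4Vectors::metadata(object)$grid
  if (is.null(g) || !is(g, "WavelengthGrid"))
    msg <- c(msg, "metadata(x)$grid must be a WavelengthGrid")
  else if (nrow(object) != nBands(g))
    msg <- c(msg, "row count differs from grid band count")
  else if (!isTRUE(all.equal(rowData(object)$wavelength_nm, wavelengths(g))))
    msg <- c(msg, "rowData wavelength_nm differs from the grid")
  if (length(msg) == 0) {
    r <- assay(object, "reflectance")
    if (any(!is.finite(r)))
      msg <- c(msg, "non-finite reflectance values")
    else if (any(r < 0))
      msg <- c(msg, "negative reflectance values")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicated sample keys")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralDataset
#'
#' @param reflectance bands x samples numeric matrix, values >= 0
#' @param grid the shared \linkS4class{WavelengthGrid}
#' @param keys data.frame with one row per sample and columns
#'   \code{season}, \code{irrigation}, \code{density}, \code{replicate}
#' @return a \linkS4class{SpectralDataset}
#' @examples
#' g <- WavelengthGrid(400, 410, 5)
#' keys <- data.frame(season = 1, irrigation = 1, density = 350,
#'                    replicate = 1:2)
#' m <- matrix(0.2, nBands(g), 2)
#' SpectralDataset(m, g, keys)
#' @export
SpectralDataset <- function(reflectance, grid, keys) {
  stopifnot(is.matrix(reflectance), is(grid, "WavelengthGrid"),
            is.data.frame(keys), nrow(keys) == ncol(reflectance))
  if (any(reflectance > 1))
    warning("reflectance values > 1 retained (specular/panel effects)")
  colnames(reflectance) <- sampleKeyString(keys)
  se <- SummarizedExperiment(
    assays = S4Vectors::SimpleList(reflectance = reflectance),
    rowData = S4Vectors::DataFrame(wavelength_nm = wavelengths(grid)),
    colData = S4Vectors::DataFrame(keys, row.names = colnames(reflectance)))
  S4Vectors::metadata(se)$grid <- grid
  new("SpectralDataset", se)
}

#' Canonical sample key string
#'
#' Builds the \code{S<season>_I<rate>_D<density>_R<rep>} label used as the
#' column name of a sample in the wide-CSV spectra layout.
#'
#' @param keys data.frame with season, irrigation, density, replicate
#' @return character vector of key strings
#' @export
sampleKeyString <- function(keys) {
  sprintf("S%d_I%.2f_D%d_R%d", as.integer(keys$season), keys$irrigation,
          as.integer(keys$density), as.integer(keys$replicate))
}

#' Parse canonical sample key strings
#'
#' Inverse of \code{\link{sampleKeyString}}.
#'
#' @param x character vector of key strings
#' @return data.frame with season, irrigation, density, replicate
#' @export
parseSampleKey <- function(x) {
  m <- regmatches(x, regexec("^S(\\d+)_I([0-9.]+)_D(\\d+)_R(\\d+)$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop("malformed sample key(s): ", paste(x[bad], collapse = ", "))
  data.frame(
    season = as.integer(vapply(m, `[`, "", 2L)),
    irrigation = as.numeric(vapply(m, `[`, "", 3L)),
    density = as.numeric(vapply(m, `[`, "", 4L)),
    replicate = as.integer(vapply(m, `[`, "", 5L)))
}

#' @rdname reflectance
setMethod("reflectance", "SpectralDataset", function(x)
  assay(x, "reflectance"))

#' @rdname sampleKeys
setMethod("sampleKeys", "SpectralDataset", function(x)
  as.data.frame(colData(x))[, c("season", "irrigation", "density",
                                "replicate")])

#' @rdname wavelengths
setMethod("wavelengths", "SpectralDataset", function(x)
  rowData(x)$wavelength_nm)

#' @rdname nBands
setMethod("nBands", "SpectralDataset", function(x) nrow(x))

#' Grid of a SpectralDataset
#'
#' @param x a \linkS4class{SpectralDataset}
#' @return the shared \linkS4class{WavelengthGrid}
#' @export
datasetGrid <- function(x) S4Vectors::metadata(x)$grid

setMethod("show", "SpectralDataset", function(object) {
  g <- datasetGrid(object)
  cat(sprintf("SpectralDataset: %d spectra, %d bands (%g-%g nm @ %g nm)\n",
              ncol(object), nrow(object), g@startNm, g@endNm, g@stepNm))
  k <- sampleKeys(object)
  cat(sprintf("  seasons: %s | irrigation: %s | densities: %s\n",
              paste(sort(unique(k$season)), collapse = ","),
              paste(format(sort(unique(k$irrigation), decreasing = TRUE),
                           nsmall = 2), collapse = ","),
              paste(sort(unique(k$density)), collapse = ",")))
})

#' SpectralIndex: a spectral reflectance index definition
#'
#' A named scalar formula over reflectances at a few fixed wavelengths.
#' Supported kinds: \code{normalized_difference}
#' ((R1 - R2)/(R1 + R2)), \code{simple_ratio} (R1/R2), \code{osavi}
#' ((R1 - R2)/(R1 + R2 + c)), \code{mtvi}
#' (a (a (R1 - R3) - b (R2 - R3)) over bands 800/670/550), and
#' \code{nmdi} (water-minus-dry SWIR difference against the 860 nm
#' reference).
#'
#' @slot name index label
#' @slot kind formula family
#' @slot bands wavelengths (nm) the formula addresses
#' @slot constants formula constants (e.g. 0.16 for OSAVI; 1.2/2.5 for MTVI)
#' @export
setClass("SpectralIndex",
  slots = c(name = "character", kind = "character", bands = "numeric",
            constants = "numeric"))

setValidity("SpectralIndex", function(object) {
  msg <- character()
  kinds <- c("normalized_difference", "simple_ratio", "osavi", "mtvi",
             "nmdi")
  if (!object@kind %in% kinds)
    msg <- c(msg, paste0("kind must be one of: ",
                         paste(kinds, collapse = ", ")))
  nb <- length(object@bands)
  need <- switch(object@kind, normalized_difference = 2L, simple_ratio = 2L,
                 osavi = 2L, mtvi = 3L, nmdi = 3L, NA_integer_)
  if (!is.na(need) && nb != need)
    msg <- c(msg, sprintf("kind '%s' needs %d bands, got %d",
                          object@kind, need, nb))
  if (length(msg)) msg else TRUE
})

#' @param name index label
#' @param kind formula family
#' @param bands wavelengths in nm
#' @param constants formula constants
#' @rdname SpectralIndex-class
#' @export
SpectralIndex <- function(name, kind, bands, constants = numeric()) {
  new("SpectralIndex", name = name, kind = kind, bands = bands,
      constants = constants)
}

setMethod("show", "SpectralIndex", function(object) {
  cat(sprintf("SpectralIndex %s [%s]: bands %s nm\n", object@name,
              object@kind, paste(object@bands, collapse = ", ")))
})

#' R2Map: coefficient-of-determination surface over band pairs
#'
#' Square matrix of R-squared values from simple linear regression of a
#' trait on the two-band normalized difference index NDI(lambda1, lambda2),
#' over all pairs of a (possibly subsampled) wavelength axis. Cells where
#' the index is constant across samples or undefined (zero denominator)
#' are masked (\code{defined = FALSE}, value stored as 0); the diagonal is
#' always masked since NDI(lambda, lambda) = 0 for every sample.
#'
#' @slot wavelengths the shared band axis (nm)
#' @slot r2 matrix of R-squared values in [0, 1]
#' @slot defined logical mask, FALSE where the cell is undefined
#' @slot trait name of the regressed trait
#' @slot n number of samples used
#' @export
setClass("R2Map",
  slots = c(wavelengths = "numeric", r2 = "matrix", defined = "matrix",
            trait = "character", n = "integer"))

setValidity("R2Map", function(object) {
  msg <- character()
  B <- length(object@wavelengths)
  if (!all(dim(object@r2) == c(B, B)) || !all(dim(object@defined) == c(B, B)))
    msg <- c(msg, "r2 and defined must be B x B for B wavelengths")
  else {
    v <- object@r2[object@defined]
    if (length(v) && (any(v < -1e-12) || any(v > 1 + 1e-12)))
      msg <- c(msg, "defined R2 values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname wavelengths
setMethod("wavelengths", "R2Map", function(x) x@wavelengths)

setMethod("show", "R2Map", function(object) {
  cat(sprintf(
    "R2Map for '%s': %d x %d bands (%g-%g nm), n = %d, max R2 = %.3f\n",
    object@trait, length(object@wavelengths), length(object@wavelengths),
    min(object@wavelengths), max(object@wavelengths), object@n,
    if (any(object@defined)) max(object@r2[object@defined]) else NA_real_))
})

#' SpectralCalibration: a fitted full-spectrum calibration model
#'
#' Holds a PLSR or SVR calibration of one trait on full-spectrum
#' reflectance, the leave-one-out cross-validation trace over candidate
#' settings (latent-factor counts for PLSR; a small hyperparameter grid
#' for SVR), and the selected setting, which minimizes RMSECV (ties at
#' numerical tolerance resolved toward the simpler setting).
#'
#' @slot method "plsr" or "svr"
#' @slot trait trait name
#' @slot wavelengths band axis of the calibration spectra
#' @slot centerX,centerY preprocessing flags (mean-centering)
#' @slot setting selected setting (ncomp, or kernel/cost/epsilon/gamma)
#' @slot candidates data.frame of candidate settings with their RMSECV
#' @slot coefficients regression vector in original band space (PLSR;
#'   empty for SVR)
#' @slot intercept intercept on the original scale (PLSR)
#' @slot xMean,yMean training means used for centering
#' @slot projection p x r matrix mapping spectra to the training row
#'   space (all methods predict in this space)
#' @slot svrModel fitted e1071 model (SVR only)
#' @slot fitted fitted values on the calibration set
#' @slot cvPred leave-one-out predictions at the selected setting
#' @slot y calibration responses
#' @export
setClass("SpectralCalibration",
  slots = c(method = "character", trait = "character",
            wavelengths = "numeric", centerX = "logical",
            centerY = "logical", setting = "list", candidates = "data.frame",
            coefficients = "numeric", intercept = "numeric",
            xMean = "numeric", yMean = "numeric", projection = "matrix",
            svrModel = "ANY", fitted = "numeric", cvPred = "numeric",
            y = "numeric"))

setMethod("show", "SpectralCalibration", function(object) {
  lab <- if (object@method == "plsr")
    sprintf("%d latent factors", object@setting$ncomp)
  else sprintf("%s kernel, cost %g", object@setting$kernel,
               object@setting$cost)
  cv <- object@cvPred
  r2cv <- cor(object@y, cv)^2
  cat(sprintf(
    "SpectralCalibration [%s] for '%s': n = %d, %d bands\n  selected: %s (RMSECV %.4g, LOO R2 %.3f)\n",
    toupper(object@method), object@trait, length(object@y),
    length(object@wavelengths), lab,
    min(object@candidates$rmsecv), r2cv))
})
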