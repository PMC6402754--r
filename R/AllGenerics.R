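#' @import methods
#' @importFrom stats aggregate approx coef cor lm pf predict pt rnorm
#'   runif sd var setNames
#' @importFrom utils read.csv write.table packageVersion
NULL

#' Wavelengths of a grid-bearing object
#'
#' Returns the vector of wavelengths (nm) spanned by a
#' \linkS4class{WavelengthGrid}, a \linkS4class{SpectralDataset} or an
#' \linkS4class{R2Map}.
#'
#' @param x the object
#' @return numeric vector of wavelengths in nm
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Number of spectral bands
#'
#' @param x a \linkS4class{WavelengthGrid} or \linkS4class{SpectralDataset}
#' @return integer band count
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' Reflectance matrix accessor
#'
#' @param x a \linkS4class{SpectralDataset}
#' @return bands x samples numeric matrix of reflectance fractions
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' Treatment keys of a dataset
#'
#' @param x a \linkS4class{SpectralDataset}
#' @return data.frame with columns season, irrigation, density, replicate
#' @export
setGeneric("sampleKeys", function(x) standardGeneric("sampleKeys"))
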