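#' Two-band normalized difference index
#'
#' NDI(lambda1, lambda2) = (R_l1 - R_l2) / (R_l1 + R_l2). Antisymmetric
#' in its bands and bounded in [-1, 1] for nonnegative reflectance.
#'
#' @param spectrum reflectance vector on \code{grid}
#' @param lambda1,lambda2 wavelengths in nm, both on the grid
#' @param grid the \linkS4class{WavelengthGrid} of \code{spectrum}
#' @return the index value
#' @examples
#' g <- WavelengthGrid()
#' s <- rep(0.2, nBands(g)); s[wavelengths(g) == 900] <- 0.4
#' normalizedDifference(s, 900, 685, g)
#' @export
normalizedDifference <- function(spectrum, lambda1, lambda2, grid) {
  r1 <- bandValue(spectrum, lambda1, grid)
  r2 <- bandValue(spectrum, lambda2, grid)
  den <- r1 + r2
  if (den == 0)
    stop(sprintf("zero denominator for NDI(%g, %g)", lambda1, lambda2))
  (r1 - r2) / den
}

# exact integer-nm band lookup on the canonical grid (no snapping)
bandValue <- function(spectrum, lambda, grid) {
  i <- match(lambda, wavelengths(grid))
  if (is.na(i))
    stop(sprintf("band %g nm is not on the grid (%g-%g @ %g nm)",
                 lambda, grid@startNm, grid@endNm, grid@stepNm))
  spectrum[i]
}

#' The twenty built-in spectral reflectance indices
#'
#' Returns the full set of 20 index definitions used throughout the
#' analysis: twelve two-band normalized difference indices selected from
#' contour-map hotspots (band pairs 548/522, 626/386, 680/1650, 840/818,
#' 1226/670, 1382/670, 1450/900, 1650/920, 2450/2100, 2498/1450,
#' 2500/2250, 2500/2470) and eight published indices: MSI (R1600/R820),
#' SRWI (R860/R1240), NWI-3 (970/880 ND), NDVI (900/685 ND), NDMI
#' (2200/1100 ND), NMDI (860, 1640, 2130), OSAVI
#' ((R800 - R670)/(R800 + R670 + 0.16)) and MTVI
#' (1.2 (1.2 (R800 - R550) - 2.5 (R670 - R550))).
#'
#' @return named list of \linkS4class{SpectralIndex} definitions,
#'   length 20
#' @export
builtinDefinitions <- function() {
  ndPairs <- list(c(548, 522), c(626, 386), c(680, 1650), c(840, 818),
                  c(1226, 670), c(1382, 670), c(1450, 900), c(1650, 920),
                  c(2450, 2100), c(2498, 1450), c(2500, 2250),
                  c(2500, 2470))
  defs <- lapply(ndPairs, function(p)
    SpectralIndex(sprintf("NDI_%d_%d", p[1], p[2]),
                  "normalized_difference", p))
  defs <- c(defs, list(
    SpectralIndex("MSI", "simple_ratio", c(1600, 820)),
    SpectralIndex("SRWI", "simple_ratio", c(860, 1240)),
    SpectralIndex("NWI3", "normalized_difference", c(970, 880)),
    SpectralIndex("NDVI", "normalized_difference", c(900, 685)),
    SpectralIndex("NDMI", "normalized_difference", c(2200, 1100)),
    SpectralIndex("NMDI", "nmdi", c(860, 1640, 2130)),
    SpectralIndex("OSAVI", "osavi", c(800, 670), constants = 0.16),
    SpectralIndex("MTVI", "mtvi", c(800, 670, 550),
                  constants = c(1.2, 2.5))))
  names(defs) <- vapply(defs, function(d) d@name, "")
  defs
}

#' Evaluate one spectral index on one spectrum
#'
#' Evaluates the formula of a \linkS4class{SpectralIndex}. The NMDI
#' default uses the standard literature grouping
#' (R860 - (R1640 - R2130)) / (R860 + (R1640 - R2130)); set
#' \code{nmdiAsPrinted = TRUE} for the variant with the plus sign in the
#' denominator's SWIR term,
#' (R860 - (R1640 - R2130)) / (R860 + (R1640 + R2130)).
#'
#' @param spectrum reflectance vector
#' @param definition a \linkS4class{SpectralIndex}
#' @param grid the \linkS4class{WavelengthGrid} of the spectrum
#' @param nmdiAsPrinted use the alternative NMDI denominator grouping
#' @return the index value
#' @export
computeIndex <- function(spectrum, definition, grid,
                         nmdiAsPrinted = FALSE) {
  b <- definition@bands
  r <- vapply(b, function(l) bandValue(spectrum, l, grid), 0)
  switch(definition@kind,
    normalized_difference = {
      den <- r[1] + r[2]
      if (den == 0) stop("zero denominator in ", definition@name)
      (r[1] - r[2]) / den
    },
    simple_ratio = {
      if (r[2] == 0) stop("zero denominator in ", definition@name)
      r[1] / r[2]
    },
    osavi = {
      c0 <- if (length(definition@constants)) definition@constants[1] else 0.16
      (r[1] - r[2]) / (r[1] + r[2] + c0)
    },
    mtvi = {
      k <- if (length(definition@constants) >= 2) definition@constants
           else c(1.2, 2.5)
      k[1] * (k[1] * (r[1] - r[3]) - k[2] * (r[2] - r[3]))
    },
    nmdi = {
      swir <- if (nmdiAsPrinted) r[2] + r[3] else r[2] - r[3]
      den <- r[1] + swir
      if (den == 0) stop("zero denominator in ", definition@name)
      (r[1] - (r[2] - r[3])) / den
    },
    stop("unknown index kind: ", definition@kind))
}

#' Index table for a whole dataset
#'
#' Evaluates a list of index definitions on every spectrum of a
#' \linkS4class{SpectralDataset}, returning one row per sample with the
#' treatment key columns followed by one column per index.
#'
#' @param dataset a \linkS4class{SpectralDataset}
#' @param definitions list of \linkS4class{SpectralIndex}; defaults to
#'   the built-in twenty
#' @param nmdiAsPrinted passed on to \code{\link{computeIndex}}
#' @return data.frame: season, irrigation, density, replicate, then one
#'   column per index, samples in dataset order
#' @export
indexTable <- function(dataset, definitions = builtinDefinitions(),
                       nmdiAsPrinted = FALSE) {
  grid <- datasetGrid(dataset)
  m <- reflectance(dataset)
  out <- sampleKeys(dataset)
  for (def in definitions) {
    vals <- vapply(seq_len(ncol(m)), function(j) {
      tryCatch(computeIndex(m[, j], def, grid, nmdiAsPrinted),
               error = function(e) stop(sprintf(
                 "index %s on sample %s: %s", def@name, colnames(m)[j],
                 conditionMessage(e)), call. = FALSE))
    }, 0)
    out[[def@name]] <- vals
  }
  out
}
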