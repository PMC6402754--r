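#' Exhaustive two-band normalized-difference R-squared map
#'
#' For every pair of wavelengths (lambda1, lambda2) on a stepped subgrid
#' of the dataset's wavelength axis, computes the coefficient of
#' determination of the ordinary least-squares regression of a trait on
#' NDI(lambda1, lambda2) across samples. With a single regressor the OLS
#' R-squared equals the squared Pearson correlation, which is what is
#' computed (vectorized one band row at a time). Cells where the index
#' is constant across samples, or undefined at any sample (zero
#' denominator), are masked; the diagonal is always masked because
#' NDI(lambda, lambda) is identically zero. The map is exactly symmetric
#' since swapping the bands flips the sign of the regressor.
#'
#' @param dataset a \linkS4class{SpectralDataset} with >= 3 samples
#' @param trait numeric vector aligned to the dataset's samples
#' @param stepNm wavelength step of the search lattice (nm); the default
#'   4 nm keeps a full 350-2500 nm map at desk scale, 1 nm gives the
#'   exhaustive map
#' @return an \linkS4class{R2Map}
#' @export
ndiR2Map <- function(dataset, trait, stepNm = 4) {
  n <- ncol(dataset)
  if (n < 3) stop("need at least 3 samples, got ", n)
  if (length(trait) != n)
    stop("trait length (", length(trait), ") differs from sample count (",
         n, ")")
  if (any(!is.finite(trait))) stop("trait contains non-finite values")
  if (stepNm < datasetGrid(dataset)@stepNm)
    stop("stepNm must be >= the dataset grid step")
  wl <- wavelengths(dataset)
  keep <- which((wl - wl[1]) %% stepNm == 0)
  wls <- wl[keep]
  R <- reflectance(dataset)[keep, , drop = FALSE]
  B <- length(wls)
  yc <- trait - mean(trait)
  syy <- sum(yc^2)
  r2 <- matrix(0, B, B)
  defined <- matrix(FALSE, B, B)
  traitConstant <- syy <= 1e-20 * max(1, mean(trait)^2) * n
  for (i in seq_len(B)) {
    A <- matrix(R[i, ], B, n, byrow = TRUE)
    den <- A + R
    num <- A - R
    ok <- rowSums(den == 0) == 0
    N <- num / den
    N[!ok, ] <- 0
    Nc <- N - rowMeans(N)
    sxx <- rowSums(Nc^2)
    # constant index across samples (incl. the diagonal) is undefined
    varOk <- sxx > (1e-12)^2 * n
    good <- ok & varOk & !traitConstant
    r <- as.vector(Nc %*% yc)
    cell <- numeric(B)
    cell[good] <- (r[good]^2) / (sxx[good] * syy)
    r2[i, ] <- cell
    defined[i, ] <- good
  }
  new("R2Map", wavelengths = wls, r2 = r2, defined = defined,
      trait = if (is.null(attr(trait, "name"))) "trait" else
        attr(trait, "name"), n = as.integer(n))
}

#' Extract hotspot regions from an R-squared map
#'
#' Finds the connected regions (4-neighbour connectivity on the band
#' lattice) of defined cells with R-squared at or above a threshold,
#' reports each region's peak cell and bounding wavelength ranges, and
#' sorts regions by peak R-squared descending. On a symmetric map each
#' off-diagonal region appears twice (mirrored across the diagonal),
#' matching the appearance of full-plane contour maps.
#'
#' @param map an \linkS4class{R2Map}
#' @param threshold hotspot cut-off, in (0, 1)
#' @return data.frame with one row per hotspot: \code{peak_r2},
#'   \code{lambda1_peak}, \code{lambda2_peak}, \code{lambda1_min},
#'   \code{lambda1_max}, \code{lambda2_min}, \code{lambda2_max},
#'   \code{n_cells}
#' @export
hotspotExtract <- function(map, threshold) {
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must be in (0, 1)")
  sel <- map@defined & map@r2 >= threshold
  empty <- data.frame(peak_r2 = numeric(), lambda1_peak = numeric(),
                      lambda2_peak = numeric(), lambda1_min = numeric(),
                      lambda1_max = numeric(), lambda2_min = numeric(),
                      lambda2_max = numeric(), n_cells = integer())
  idx <- which(sel, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  B <- nrow(sel)
  cellId <- (idx[, 2] - 1L) * B + idx[, 1]
  pos <- integer(B * B)
  pos[cellId] <- seq_along(cellId)
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L))) {     # right and down neighbours
    ni <- idx[, 1] + d[1]; nj <- idx[, 2] + d[2]
    inb <- ni >= 1 & ni <= B & nj >= 1 & nj <= B
    nid <- (nj - 1L) * B + ni
    hit <- inb & nid >= 1 & nid <= B * B
    hit[hit] <- pos[nid[hit]] > 0
    if (any(hit))
      edges <- c(edges, rbind(seq_along(cellId)[hit], pos[nid[hit]]))
  }
  g <- igraph::make_graph(edges = edges, n = nrow(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  wls <- map@wavelengths
  res <- lapply(seq_len(max(comp)), function(k) {
    cells <- which(comp == k)
    vals <- map@r2[idx[cells, , drop = FALSE]]
    top <- cells[which.max(vals)]
    data.frame(peak_r2 = max(vals),
               lambda1_peak = wls[idx[top, 1]],
               lambda2_peak = wls[idx[top, 2]],
               lambda1_min = min(wls[idx[cells, 1]]),
               lambda1_max = max(wls[idx[cells, 1]]),
               lambda2_min = min(wls[idx[cells, 2]]),
               lambda2_max = max(wls[idx[cells, 2]]),
               n_cells = length(cells))
  })
  out <- do.call(rbind, res)
  out[order(-out$peak_r2), , drop = FALSE]
}
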