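#' Simple linear regression summary
#'
#' Ordinary least-squares fit of y on x with the scalar summaries used
#' throughout the index-trait tables: slope, intercept, R-squared
#' (squared Pearson correlation, identical to the OLS R-squared with one
#' regressor), and the two-sided p-value of the slope from the t
#' statistic on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return list with \code{n}, \code{slope}, \code{intercept}, \code{r2},
#'   \code{p}, and \code{defined} (FALSE when x is constant, in which
#'   case the estimates are NA)
#' @export
simpleLinearFit <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations, got ", n)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in x or y")
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (sxx <= 0)
    return(list(n = n, slope = NA_real_, intercept = NA_real_,
                r2 = NA_real_, p = NA_real_, defined = FALSE))
  sxy <- sum(xc * yc); syy <- sum(yc^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (syy > 0) (sxy^2) / (sxx * syy) else 1
  r2 <- min(max(r2, 0), 1)
  p <- if (r2 >= 1) 0 else {
    tval <- sqrt(r2 * (n - 2) / (1 - r2))
    2 * pt(tval, df = n - 2, lower.tail = FALSE)
  }
  list(n = n, slope = slope, intercept = intercept, r2 = r2, p = p,
       defined = TRUE)
}

#' Replicate means of indices and traits
#'
#' Averages per-plot index values and trait values over replicates
#' within season x irrigation x density cells. Indices are computed per
#' plot first and then averaged (index formulas are nonlinear in the
#' spectrum, so the order matters; the derived quantities, not the
#' spectra, are what the treatment-mean regressions operate on).
#'
#' @param tab data.frame with key columns season, irrigation, density,
#'   replicate plus numeric value columns
#' @return data.frame with one row per season x irrigation x density and
#'   replicate-averaged value columns
#' @export
replicateMeans <- function(tab) {
  valCols <- setdiff(colnames(tab),
                     c("season", "irrigation", "density", "replicate"))
  agg <- aggregate(tab[valCols],
                   by = tab[c("season", "irrigation", "density")], mean)
  agg[order(agg$season, -agg$irrigation, agg$density), , drop = FALSE]
}

#' Grouping schemes of the index-trait regression tables
#'
#' @return character vector of the five scheme names
#' @export
groupingSchemes <- function()
  c("per_irrigation", "per_density", "pooled_rates_means",
    "pooled_density_means", "all_pooled")

# aggregates the replicate-mean records according to one scheme and
# returns a list of groups, each a data.frame of records to regress over
schemeGroups <- function(base, scheme) {
  valCols <- setdiff(colnames(base), c("season", "irrigation", "density"))
  switch(scheme,
    per_irrigation = {
      g <- split(base, base$irrigation)
      names(g) <- sprintf("I%.2f", as.numeric(names(g)))
      g[order(names(g), decreasing = TRUE)]
    },
    per_density = {
      g <- split(base, base$density)
      names(g) <- sprintf("D%s", names(g))
      g
    },
    pooled_rates_means = {
      agg <- aggregate(base[valCols],
                       by = base[c("season", "irrigation")], mean)
      list(all_rates = agg)
    },
    pooled_density_means = {
      agg <- aggregate(base[valCols],
                       by = base[c("season", "density")], mean)
      list(all_densities = agg)
    },
    all_pooled = list(pooled = base),
    stop("unknown scheme: ", scheme))
}

#' Index-trait regressions under a grouping scheme
#'
#' Reproduces the structure of the treatment-subset regression tables:
#' simple linear regressions between every index column and every trait,
#' within the groups defined by one of five schemes. All schemes start
#' from replicate means per season x irrigation x density cell (30
#' records on the reference design of 2 seasons x 3 rates x 5
#' densities): \code{per_irrigation} regresses within each rate (n = 10),
#' \code{per_density} within each density (n = 6),
#' \code{pooled_rates_means} averages over densities within each
#' rate x season first (n = 6), \code{pooled_density_means} averages over
#' rates within each density x season (n = 10), and \code{all_pooled}
#' uses all records (n = 30). Significance stars mark p <= 0.05 (*),
#' 0.01 (**) and 0.001 (***).
#'
#' @param indexMatrix per-plot index table from \code{\link{indexTable}}
#' @param agronomy per-plot trait table with the same key columns and
#'   trait value columns
#' @param scheme one of \code{\link{groupingSchemes}}
#' @param traits trait columns to regress; defaults to all non-key
#'   numeric columns of \code{agronomy}
#' @return tidy data.frame: index, trait, scheme, group, n, slope,
#'   intercept, r2, p, stars, significant
#' @export
subsetRegressions <- function(indexMatrix, agronomy, scheme,
                              traits = NULL) {
  scheme <- match.arg(scheme, groupingSchemes())
  keyCols <- c("season", "irrigation", "density", "replicate")
  if (!all(keyCols %in% colnames(indexMatrix)) ||
      !all(keyCols %in% colnames(agronomy)))
    stop("both tables need key columns ", paste(keyCols, collapse = ", "))
  idxCols <- setdiff(colnames(indexMatrix), keyCols)
  if (is.null(traits)) traits <- setdiff(colnames(agronomy), keyCols)
  merged <- merge(indexMatrix, agronomy[, c(keyCols, traits)],
                  by = keyCols, sort = FALSE)
  if (nrow(merged) != nrow(indexMatrix))
    stop("index and agronomy tables do not align on treatment keys")
  base <- replicateMeans(merged)
  groups <- schemeGroups(base, scheme)
  rows <- list()
  for (gname in names(groups)) {
    gdat <- groups[[gname]]
    if (nrow(gdat) < 3) {
      warning(sprintf("group %s skipped: n = %d < 3", gname, nrow(gdat)))
      next
    }
    for (idx in idxCols) for (tr in traits) {
      f <- simpleLinearFit(gdat[[idx]], gdat[[tr]])
      rows[[length(rows) + 1L]] <- data.frame(
        index = idx, trait = tr, scheme = scheme, group = gname,
        n = f$n, slope = f$slope, intercept = f$intercept, r2 = f$r2,
        p = f$p, stars = starsFor(f$p),
        significant = isTRUE(f$p <= 0.05))
    }
  }
  do.call(rbind, rows)
}

starsFor <- function(p) {
  if (is.na(p)) return("")
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else
    if (p <= 0.05) "*" else ""
}

#' Yield-ET production function
#'
#' Linear fit of grain yield on seasonal crop evapotranspiration. The
#' slope is the yield gain per mm of ET and the basal seasonal ET (the ET
#' at which the fitted line crosses zero yield) is -intercept/slope,
#' reported only for a positive slope.
#'
#' @param gy grain yield (g m-2)
#' @param et seasonal crop evapotranspiration (mm)
#' @return list with the \code{\link{simpleLinearFit}} fields plus
#'   \code{basalEt} (NA with \code{basalDefined = FALSE} when the slope
#'   is not positive)
#' @export
productionFunction <- function(gy, et) {
  if (diff(range(et)) <= 0) stop("ET values must span a positive range")
  f <- simpleLinearFit(et, gy)
  if (f$defined && f$slope > 0) {
    f$basalEt <- -f$intercept / f$slope
    f$basalDefined <- TRUE
  } else {
    f$basalEt <- NA_real_
    f$basalDefined <- FALSE
  }
  f
}
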