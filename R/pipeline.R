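#' Pipeline run configuration
#'
#' Assembles paths, stage toggles and analysis settings for
#' \code{\link{runPipeline}}. Stages run in the fixed order simulate,
#' indices, contour, regress, waterbudget, mvmodel; disabled stages are
#' skipped. When \code{simulate} is disabled, \code{spectraPath} and
#' \code{agronomyPath} must point at existing files written in the
#' package's CSV layouts.
#'
#' @param outputDir directory for the report bundle (created)
#' @param stages character vector of stages to run
#' @param config \code{\link{syntheticConfig}} for the simulate stage
#' @param spectraPath,agronomyPath input files when simulate is off
#' @param contourStepNm band-search lattice step (nm)
#' @param contourTraits traits to map
#' @param schemes regression grouping schemes to run
#' @param methods multivariate methods to fit
#' @param mvTraits traits to calibrate
#' @param seed integer seed for the whole run
#' @return an object of class \code{PipelineConfig}
#' @export
pipelineConfig <- function(outputDir,
                           stages = c("simulate", "indices", "contour",
                                      "regress", "waterbudget", "mvmodel"),
                           config = syntheticConfig(),
                           spectraPath = NULL, agronomyPath = NULL,
                           contourStepNm = 10,
                           contourTraits = c("GLA", "TDW", "GY", "WUE"),
                           schemes = groupingSchemes(),
                           methods = c("plsr", "svr"),
                           mvTraits = "GY",
                           seed = 1L) {
  known <- c("simulate", "indices", "contour", "regress", "waterbudget",
             "mvmodel")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!"simulate" %in% stages) {
    for (p in c(spectraPath, agronomyPath))
      if (is.null(p) || !file.exists(p))
        stop("input file missing with simulate disabled: ",
             if (is.null(p)) "(not set)" else p)
  }
  structure(list(outputDir = outputDir, stages = stages, config = config,
                 spectraPath = spectraPath, agronomyPath = agronomyPath,
                 contourStepNm = contourStepNm,
                 contourTraits = contourTraits, schemes = schemes,
                 methods = methods, mvTraits = mvTraits,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

writeCsv <- function(df, path) {
  write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double")
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end and writes a deterministic report
#' bundle of plain CSV/JSON files plus a manifest listing every written
#' file with its MD5 checksum, the seed and the package version.
#' Identical configuration and seed give identical bundle checksums.
#'
#' Stage outputs: \code{spectra.csv}, \code{agronomy.csv},
#' \code{water.csv} (simulate); \code{index_table.csv} (indices);
#' \code{contour_<trait>.csv} and \code{contour_axes.json} (contour);
#' \code{regressions.csv} (regress); \code{ky_table.csv} and
#' \code{production_function.csv} (waterbudget);
#' \code{calibration_<method>_<trait>.csv} (mvmodel).
#'
#' @param cfg a \code{\link{pipelineConfig}}
#' @return the manifest, invisibly (also written as
#'   \code{manifest.json})
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  spectra <- NULL; agronomy <- NULL; water <- NULL
  if ("simulate" %in% cfg$stages) stage("simulate", {
    conf <- cfg$config
    conf$seed <- cfg$seed
    exp <- generateExperiment(conf)
    spectra <- exp$spectra; agronomy <- exp$agronomy; water <- exp$water
    files <- c(files,
               writeSpectra(spectra, file.path(cfg$outputDir, "spectra.csv")),
               writeCsv(agronomy, file.path(cfg$outputDir, "agronomy.csv")),
               writeCsv(water, file.path(cfg$outputDir, "water.csv")))
  }) else stage("load", {
    spectra <- readSpectra(cfg$spectraPath)
    agronomy <- read.csv(cfg$agronomyPath)
  })
  idx <- NULL
  if ("indices" %in% cfg$stages) stage("indices", {
    idx <- indexTable(spectra)
    files <- c(files, writeCsv(idx, file.path(cfg$outputDir,
                                              "index_table.csv")))
  })
  if ("contour" %in% cfg$stages) stage("contour", {
    for (tr in cfg$contourTraits) {
      y <- traitPerSample(agronomy, spectra, tr)
      map <- ndiR2Map(spectra, y, stepNm = cfg$contourStepNm)
      m <- map@r2
      m[!map@defined] <- NA
      df <- as.data.frame(m)
      colnames(df) <- map@wavelengths
      files <- c(files, writeCsv(
        cbind(wavelength_nm = map@wavelengths, df),
        file.path(cfg$outputDir, sprintf("contour_%s.csv", tr))))
    }
    axes <- list(step_nm = cfg$contourStepNm, traits = cfg$contourTraits)
    p <- file.path(cfg$outputDir, "contour_axes.json")
    jsonlite::write_json(axes, p, auto_unbox = TRUE)
    files <- c(files, p)
  })
  if ("regress" %in% cfg$stages) stage("regress", {
    if (is.null(idx)) idx <- indexTable(spectra)
    res <- do.call(rbind, lapply(cfg$schemes, function(s)
      subsetRegressions(idx, agronomy, s)))
    files <- c(files, writeCsv(res, file.path(cfg$outputDir,
                                              "regressions.csv")))
  })
  if ("waterbudget" %in% cfg$stages) stage("waterbudget", {
    ky <- kyAnalysis(agronomy)
    files <- c(files, writeCsv(ky$perCombination,
                               file.path(cfg$outputDir, "ky_table.csv")))
    files <- c(files, writeCsv(ky$production,
                               file.path(cfg$outputDir,
                                         "production_function.csv")))
  })
  if ("mvmodel" %in% cfg$stages) stage("mvmodel", {
    X <- t(reflectance(spectra))
    for (m in cfg$methods) for (tr in cfg$mvTraits) {
      y <- traitPerSample(agronomy, spectra, tr)
      mod <- fitCalibration(X, y, method = m,
                            wavelengths = wavelengths(spectra))
      rep <- subsetValidationSuite(mod, spectra, y)
      files <- c(files, writeCsv(rep, file.path(
        cfg$outputDir, sprintf("calibration_%s_%s.csv", m, tr))))
    }
  })
  manifest <- list(
    package = "specyield",
    version = as.character(packageVersion("specyield")),
    seed = cfg$seed,
    stages = cfg$stages,
    files = lapply(sort(unique(files)), function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest,
                       file.path(cfg$outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# trait values aligned to the dataset's sample order
traitPerSample <- function(agronomy, dataset, trait) {
  keys <- sampleKeys(dataset)
  m <- merge(cbind(keys, .ord = seq_len(nrow(keys))), agronomy,
             by = c("season", "irrigation", "density", "replicate"),
             sort = FALSE)
  if (nrow(m) != nrow(keys))
    stop("agronomy table does not align with dataset keys")
  y <- m[[trait]][order(m$.ord)]
  attr(y, "name") <- trait
  y
}

#' Per-combination and pooled yield response factors
#'
#' Computes seasonal replicate-mean GY and ET per treatment cell, the
#' relative deficits and decreases of each deficit x density combination
#' against the full-irrigation reference at the same density, the ky per
#' combination, the pooled through-origin ky per season, and the
#' seasonal production function (GY on ET with its basal ET).
#'
#' @param agronomy per-plot agronomy table with GY and ET columns
#' @return list with \code{perCombination}, \code{pooled} (per-season
#'   ky), and \code{production} (per-season production-function fits)
#' @export
kyAnalysis <- function(agronomy) {
  cellMeans <- aggregate(agronomy[c("GY", "ET")],
                         by = agronomy[c("season", "irrigation",
                                         "density")], mean)
  rates <- sort(unique(cellMeans$irrigation), decreasing = TRUE)
  full <- rates[1]
  per <- list()
  for (s in unique(cellMeans$season)) for (d in unique(cellMeans$density))
    for (w in rates[-1]) {
      ref <- cellMeans[cellMeans$season == s & cellMeans$density == d &
                       cellMeans$irrigation == full, ]
      act <- cellMeans[cellMeans$season == s & cellMeans$density == d &
                       cellMeans$irrigation == w, ]
      if (!nrow(ref) || !nrow(act)) next
      k <- kySingle(act$ET, ref$ET, act$GY, ref$GY)
      per[[length(per) + 1L]] <- data.frame(
        season = s, irrigation = w, density = d, deficit = k$deficit,
        decrease = k$decrease, ky = k$ky, ky_2dp = k$kyRounded)
    }
  perCombination <- do.call(rbind, per)
  pooled <- data.frame(season = sort(unique(perCombination$season)))
  pooled$ky <- vapply(pooled$season, function(s) {
    sel <- perCombination$season == s
    kyPooled(perCombination$deficit[sel], perCombination$decrease[sel])
  }, 0)
  production <- do.call(rbind, lapply(unique(agronomy$season), function(s) {
    sel <- agronomy$season == s
    f <- productionFunction(agronomy$GY[sel], agronomy$ET[sel])
    data.frame(season = s, slope = f$slope, intercept = f$intercept,
               r2 = f$r2, p = f$p, basal_et = f$basalEt)
  }))
  list(perCombination = perCombination, pooled = pooled,
       production = production)
}
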