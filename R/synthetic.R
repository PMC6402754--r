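#' Configuration of a synthetic irrigation x density experiment
#'
#' Describes the crossed design and the response-surface, water-budget
#' and noise parameters of the synthetic experiment generator. The
#' defaults emulate the reference field study: two growing seasons,
#' irrigation at 1.00/0.75/0.50 of estimated crop ET, five plant
#' densities (150-550 seeds m-2), three replicates, full-irrigation
#' seasonal water of 558 and 555 mm with 38 and 45 mm sowing
#' applications, a pooled yield response factor of 1.3, and a grain
#' yield surface concave in density whose optimum (350 seeds m-2 under
#' full irrigation) moves toward lower densities as the deficit grows.
#'
#' @param seasons number of growing seasons
#' @param irrigationRates ET fractions applied
#' @param densities sowing densities (seeds m-2), strictly increasing
#' @param replicates replicates per treatment cell
#' @param grid \linkS4class{WavelengthGrid} of the generated spectra
#' @param densityOptimum density maximizing yield under full irrigation
#'   (seeds m-2)
#' @param densityShift downward shift of the optimum per unit of
#'   irrigation deficit (seeds m-2); the interaction strength
#' @param densityCurvature,densityScale curvature and width (seeds m-2)
#'   of the concave density response
#' @param kyGen pooled yield response factor built into the yield
#'   surface; the irrigation slope
#' @param gyPeak peak grain yield (g m-2) per season at full irrigation
#'   and optimum density
#' @param tdwRatio aboveground dry weight per unit grain yield
#' @param glaScale green leaf area (cm2 plant-1) per unit LAI at unit
#'   relative density
#' @param fullIrrigation seasonal irrigation water of the full (1.00)
#'   treatment, per season (mm)
#' @param sowingWater sowing application per season (mm)
#' @param seasonRain effective precipitation per season (mm)
#' @param deepPercBase deep percolation of the full treatment (mm);
#'   scales with the irrigation fraction
#' @param deltaS mean storage change sowing-minus-harvest (mm)
#' @param deltaSSd plot-level standard deviation of the storage change
#' @param laiMax leaf area index ceiling of a dense full-irrigation
#'   canopy
#' @param densitySat density (seeds m-2) at which canopy closure
#'   saturates
#' @param seasonFactor multiplicative latent offset per season
#' @param spectralNoiseSd multiplicative spectral noise sd (fraction)
#' @param latentCV plot-level coefficient of variation of the latent
#'   canopy state (visible in the spectra)
#' @param agronomicCV measurement coefficient of variation of the
#'   agronomic traits (not visible in the spectra)
#' @param seed integer RNG seed
#' @return an object of class \code{SyntheticConfig}
#' @export
syntheticConfig <- function(seasons = 2L,
                            irrigationRates = c(1.00, 0.75, 0.50),
                            densities = c(150, 250, 350, 450, 550),
                            replicates = 3L,
                            grid = WavelengthGrid(),
                            densityOptimum = 350,
                            densityShift = 150,
                            densityCurvature = 0.5,
                            densityScale = 400,
                            kyGen = 1.3,
                            gyPeak = c(950, 905),
                            tdwRatio = 2.4,
                            glaScale = 110,
                            fullIrrigation = c(558, 555),
                            sowingWater = c(38, 45),
                            seasonRain = c(45, 40),
                            deepPercBase = 25,
                            deltaS = 8,
                            deltaSSd = 2,
                            laiMax = 4.2,
                            densitySat = 250,
                            seasonFactor = c(1, 0.96),
                            spectralNoiseSd = 0.01,
                            latentCV = 0.02,
                            agronomicCV = 0.05,
                            seed = 1L) {
  cfg <- list(seasons = as.integer(seasons),
              irrigationRates = irrigationRates, densities = densities,
              replicates = as.integer(replicates), grid = grid,
              densityOptimum = densityOptimum, densityShift = densityShift,
              densityCurvature = densityCurvature,
              densityScale = densityScale, kyGen = kyGen, gyPeak = gyPeak,
              tdwRatio = tdwRatio, glaScale = glaScale,
              fullIrrigation = fullIrrigation, sowingWater = sowingWater,
              seasonRain = seasonRain, deepPercBase = deepPercBase,
              deltaS = deltaS, deltaSSd = deltaSSd, laiMax = laiMax,
              densitySat = densitySat, seasonFactor = seasonFactor,
              spectralNoiseSd = spectralNoiseSd, latentCV = latentCV,
              agronomicCV = agronomicCV, seed = as.integer(seed))
  validateSyntheticConfig(cfg)
  structure(cfg, class = "SyntheticConfig")
}

validateSyntheticConfig <- function(cfg) {
  bad <- character()
  if (!(cfg$seasons >= 1)) bad <- c(bad, "seasons")
  if (!(cfg$replicates >= 1)) bad <- c(bad, "replicates")
  if (!length(cfg$irrigationRates) ||
      any(cfg$irrigationRates <= 0 | cfg$irrigationRates > 1))
    bad <- c(bad, "irrigationRates")
  if (length(cfg$densities) < 1 || any(diff(cfg$densities) <= 0) ||
      any(cfg$densities <= 0))
    bad <- c(bad, "densities")
  for (f in c("spectralNoiseSd", "latentCV", "agronomicCV", "deltaSSd"))
    if (cfg[[f]] < 0) bad <- c(bad, f)
  for (f in c("gyPeak", "fullIrrigation", "kyGen", "laiMax", "glaScale",
              "tdwRatio", "densityOptimum", "densityScale", "densitySat"))
    if (any(cfg[[f]] <= 0)) bad <- c(bad, f)
  if (length(bad))
    stop("invalid synthetic config field(s): ",
         paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

# recycle a per-season parameter
perSeason <- function(v, s) v[((s - 1L) %% length(v)) + 1L]

# deterministic per-record RNG seed keyed by (seed, record index) so that
# subsetting the design never changes generated values
recordSeed <- function(seed, i)
  as.integer((as.numeric(seed) * 1000003 + i * 7919) %% 2147483587L) + 1L

#' Latent canopy state of one plot
#'
#' The generator links treatments to spectra and traits through a small
#' latent state: fractional vegetation cover, leaf area index, a canopy
#' chlorophyll proxy and a canopy water proxy.
#'
#' @param cover fractional vegetation cover in [0, 1]
#' @param lai leaf area index, >= 0
#' @param chlorophyll canopy chlorophyll proxy, >= 0
#' @param water canopy water proxy, >= 0
#' @return an object of class \code{LatentPlotState}
#' @export
latentPlotState <- function(cover, lai, chlorophyll, water) {
  if (!(cover >= 0 && cover <= 1)) stop("cover must be in [0, 1]")
  for (v in c(lai = lai, chlorophyll = chlorophyll, water = water))
    if (!is.finite(v) || v < 0)
      stop("latent proxies must be finite and nonnegative")
  structure(list(cover = cover, lai = lai, chlorophyll = chlorophyll,
                 water = water), class = "LatentPlotState")
}

#' Bare-soil reflectance endmember
#'
#' Smooth analytic bright-soil curve used by the linear mixture model of
#' \code{\link{canopySpectrum}}.
#'
#' @param wl wavelengths (nm)
#' @return reflectance fractions
#' @export
soilEndmember <- function(wl)
  0.10 + 0.25 / (1 + exp(-(wl - 1000) / 600))

# vegetation endmember: green peak near 550 nm, chlorophyll-scaled red
# absorption near 670 nm, an NIR plateau saturating as 1 - exp(-k LAI),
# and water-scaled absorption troughs near 1450 and 1940 nm
vegetationEndmember <- function(wl, state) {
  visible <- 0.05 + 0.10 * exp(-((wl - 550) / 40)^2) -
    0.04 * min(state$chlorophyll, 1) * exp(-((wl - 670) / 35)^2)
  plateauShape <- 0.45 / (1 + exp(-(wl - 715) / 12)) *
    (1 - 0.30 / (1 + exp(-(wl - 1350) / 200)))
  nir <- plateauShape * (1 - exp(-0.6 * state$lai))
  troughs <- 1 - min(state$water, 1) *
    (0.55 * exp(-((wl - 1450) / 55)^2) + 0.65 * exp(-((wl - 1940) / 75)^2))
  pmin(pmax((visible + nir) * troughs, 0), 1)
}

#' Synthesize one canopy reflectance spectrum
#'
#' Linear mixture of a vegetation endmember and a bare-soil endmember
#' weighted by fractional cover, followed by multiplicative noise and
#' clamping to [0, 1]. The vegetation endmember carries the qualitative
#' structure of a green canopy: a green peak near 550 nm,
#' chlorophyll-scaled absorption near 670 nm, an NIR plateau saturating
#' with leaf area index, and water-scaled absorption troughs near 1450
#' and 1940 nm, so that denser, wetter canopies darken the visible and
#' SWIR regions while brightening the NIR.
#'
#' @param state a \code{\link{latentPlotState}}
#' @param grid \linkS4class{WavelengthGrid}
#' @param noiseSd multiplicative noise sd (0 disables noise)
#' @param seed optional seed for the noise draw
#' @return reflectance vector on the grid, in [0, 1]
#' @export
canopySpectrum <- function(state, grid, noiseSd = 0, seed = NULL) {
  stopifnot(inherits(state, "LatentPlotState"))
  wl <- wavelengths(grid)
  refl <- state$cover * vegetationEndmember(wl, state) +
    (1 - state$cover) * soilEndmember(wl)
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    refl <- refl * (1 + rnorm(length(wl), 0, noiseSd))
  }
  pmin(pmax(refl, 0), 1)
}

# deterministic water-budget components of one treatment (no plot noise)
waterComponents <- function(cfg, season, w) {
  list(etc = w * perSeason(cfg$fullIrrigation, season),
       p = perSeason(cfg$seasonRain, season) +
         perSeason(cfg$sowingWater, season),
       d = cfg$deepPercBase * w)
}

# deterministic seasonal ET of a treatment at the mean storage change
deterministicEt <- function(cfg, season, w) {
  comp <- waterComponents(cfg, season, w)
  seasonalEt(comp$etc, p = comp$p, d = comp$d, deltaS = cfg$deltaS)
}

# concave density response with deficit-shifted optimum
densityResponse <- function(cfg, d, w) {
  dopt <- cfg$densityOptimum - cfg$densityShift * (1 - w)
  1 - cfg$densityCurvature * ((d - dopt) / cfg$densityScale)^2
}

# deterministic grain-yield surface (g m-2)
gySurface <- function(cfg, season, w, d) {
  etm <- deterministicEt(cfg, season, 1)
  eta <- deterministicEt(cfg, season, w)
  def <- 1 - eta / etm
  perSeason(cfg$gyPeak, season) * (1 - cfg$kyGen * def) *
    densityResponse(cfg, d, w)
}

# deterministic latent canopy state of a treatment cell
latentSurface <- function(cfg, season, w, d) {
  sf <- perSeason(cfg$seasonFactor, season)
  lai <- cfg$laiMax * (1 - exp(-d / cfg$densitySat)) *
    (0.35 + 0.65 * w) * sf
  chl <- (0.45 + 0.55 * w) * sf
  list(lai = lai, chl = chl)
}

#' Basal seasonal ET implied by a synthetic configuration
#'
#' The yield surface of the generator is linear in seasonal ET at fixed
#' density, crossing zero yield at ETm (ky - 1)/ky; this is the basal ET
#' that \code{\link{productionFunction}} recovers from generated data.
#'
#' @param config a \code{\link{syntheticConfig}}
#' @param season season index
#' @return basal seasonal ET (mm)
#' @export
generatorBasalEt <- function(config, season = 1) {
  etm <- deterministicEt(config, season, 1)
  etm * (config$kyGen - 1) / config$kyGen
}

#' Generate a full synthetic experiment
#'
#' Produces one record per season x irrigation rate x density x
#' replicate: a canopy reflectance spectrum (through
#' \code{\link{canopySpectrum}} from the plot's latent state), the
#' agronomy table (GLA, TDW, GY, WUE) and the per-plot water-balance
#' components. The deterministic response surface has grain yield and
#' dry weight increasing with irrigation at fixed density, concave in
#' density with the optimum moving to lower densities as the deficit
#' grows, and WUE = GY / seasonal ET holds exactly in every record. All
#' randomness is keyed by (seed, record index), so the same config and
#' seed give bit-identical output and subsetting the design does not
#' change generated values.
#'
#' @param config a \code{\link{syntheticConfig}}
#' @return list with \code{spectra} (a \linkS4class{SpectralDataset}),
#'   \code{agronomy} (data.frame with keys and GLA, TDW, GY, WUE, ET),
#'   \code{water} (data.frame of water-balance components), and
#'   \code{signal} (the noise-free trait surface per record, useful for
#'   noise-ceiling accounting)
#' @export
generateExperiment <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- config
  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        density = cfg$densities,
                        irrigation = cfg$irrigationRates,
                        season = seq_len(cfg$seasons))
  design <- design[, c("season", "irrigation", "density", "replicate")]
  nrec <- nrow(design)
  wl <- wavelengths(cfg$grid)
  refl <- matrix(0, length(wl), nrec)
  agro <- design
  water <- design
  signal <- design
  for (i in seq_len(nrec)) {
    s <- design$season[i]; w <- design$irrigation[i]
    d <- design$density[i]
    set.seed(recordSeed(cfg$seed, i))
    lat0 <- latentSurface(cfg, s, w, d)
    lai <- lat0$lai * exp(rnorm(1, 0, cfg$latentCV))
    chl <- max(lat0$chl * exp(rnorm(1, 0, cfg$latentCV / 2)), 0)
    cover <- 1 - exp(-0.6 * lai)
    wat <- min((0.35 + 0.65 * w) * cover *
                 exp(rnorm(1, 0, cfg$latentCV / 2)), 1)
    state <- latentPlotState(cover, lai, chl, wat)
    refl[, i] <- canopySpectrum(state, cfg$grid, cfg$spectralNoiseSd,
                                seed = recordSeed(cfg$seed, i) + 1L)
    comp <- waterComponents(cfg, s, w)
    dS <- cfg$deltaS + rnorm(1, 0, cfg$deltaSSd)
    et <- seasonalEt(comp$etc, p = comp$p, d = comp$d, deltaS = dS)
    gy0 <- gySurface(cfg, s, w, d)
    gla0 <- cfg$glaScale * lat0$lai / (d / cfg$densityOptimum)
    tdw0 <- cfg$tdwRatio * gy0
    gy <- gy0 * (1 + rnorm(1, 0, cfg$agronomicCV))
    gla <- gla0 * (1 + rnorm(1, 0, cfg$agronomicCV))
    tdw <- tdw0 * (1 + rnorm(1, 0, cfg$agronomicCV))
    agro$GLA[i] <- gla
    agro$TDW[i] <- tdw
    agro$GY[i] <- gy
    agro$ET[i] <- et
    agro$WUE[i] <- gy / et
    water$etc[i] <- comp$etc
    water$p[i] <- comp$p
    water$cr[i] <- 0
    water$runoff[i] <- 0
    water$d[i] <- comp$d
    water$deltaS[i] <- dS
    water$et[i] <- et
    signal$GLA[i] <- gla0
    signal$TDW[i] <- tdw0
    signal$GY[i] <- gy0
    signal$ET[i] <- deterministicEt(cfg, s, w)
    signal$WUE[i] <- gy0 / signal$ET[i]
  }
  spectra <- SpectralDataset(refl, cfg$grid, design)
  list(spectra = spectra, agronomy = agro, water = water, signal = signal)
}

#' Generate a daily meteorological series
#'
#' Plausible arid-site daily records for a winter wheat season sown on
#' December 1st: bounded temperatures with max above min, relative
#' humidity in (0, 100), positive wind speed and nonnegative net
#' radiation, with monthly centers following the site's climate normals
#' (December through April: mean temperatures 16.4, 14.6, 17.3, 21.5 and
#' 26.9 degrees C). Saturation and actual vapour pressure, the
#' saturation-slope Delta and the psychrometric constant gamma are
#' derived with the standard FAO-56 formulas (station elevation 400 m).
#'
#' @param days season length in days, >= 1
#' @param seed RNG seed; equal seeds give identical series
#' @param elevation station elevation (m) for the psychrometric constant
#' @return data.frame with one row per day: day, month, tmax, tmin,
#'   tmean, rh, u2, rn, g, es, ea, delta, gamma
#' @export
generateMetSeries <- function(days, seed = 1L, elevation = 400) {
  if (days < 1) stop("days must be >= 1")
  normals <- data.frame(
    month = c(12, 1, 2, 3, 4),
    tmax = c(22.2, 20.2, 23.4, 27.7, 33.4),
    tmin = c(10.6, 9.0, 11.2, 15.2, 20.4),
    rh = c(47, 51, 41, 36, 34),
    rn = c(8.5, 9.0, 11.5, 14.0, 16.5))
  monthLen <- c(31, 31, 28, 31, 30)   # Dec, Jan, Feb, Mar, Apr
  monthIdx <- rep(seq_len(5), times = monthLen)
  monthIdx <- rep_len(monthIdx, days)
  set.seed(seed)
  nm <- normals[monthIdx, ]
  tmax <- nm$tmax + rnorm(days, 0, 1.5)
  tmin <- nm$tmin + rnorm(days, 0, 1.2)
  tmax <- pmax(tmax, tmin + 1)
  tmean <- (tmax + tmin) / 2
  rh <- pmin(pmax(nm$rh + rnorm(days, 0, 5), 5), 95)
  u2 <- exp(rnorm(days, log(2), 0.3))
  rn <- pmax(nm$rn + rnorm(days, 0, 1), 0.5)
  e0 <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  es <- (e0(tmax) + e0(tmin)) / 2
  ea <- es * rh / 100
  delta <- 4098 * e0(tmean) / (tmean + 237.3)^2
  pressure <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  data.frame(day = seq_len(days), month = nm$month, tmax = tmax,
             tmin = tmin, tmean = tmean, rh = rh, u2 = u2, rn = rn,
             g = 0, es = es, ea = ea, delta = delta,
             gamma = 0.000665 * pressure)
}
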