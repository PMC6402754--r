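#' FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Daily reference evapotranspiration (mm day-1) of the standard grass
#' surface,
#' \deqn{ETo = \frac{0.408\,\Delta (R_n - G) + \gamma \frac{900}{T+273}
#'   u_2 (e_s - e_a)}{\Delta + \gamma (1 + 0.34\, u_2)}}
#' with net radiation Rn and soil heat flux G in MJ m-2 day-1, mean air
#' temperature T in degrees C, wind speed u2 in m s-1 at 2 m,
#' saturation/actual vapour pressure es/ea in kPa, psychrometric
#' constant gamma and saturation-slope Delta in kPa per degree C.
#' Vectorized over days; the result is truncated at zero.
#'
#' @param met data.frame with columns \code{rn}, \code{g}, \code{tmean},
#'   \code{u2}, \code{es}, \code{ea}, \code{delta}, \code{gamma} (as
#'   produced by \code{\link{generateMetSeries}})
#' @return numeric vector of daily ETo (mm day-1)
#' @export
penmanMonteithEto <- function(met) {
  need <- c("rn", "g", "tmean", "u2", "es", "ea", "delta", "gamma")
  miss <- setdiff(need, colnames(met))
  if (length(miss)) stop("met misses columns: ", paste(miss, collapse = ", "))
  with(met, {
    if (any(es < ea - 1e-12)) stop("es must be >= ea")
    if (any(u2 < 0)) stop("u2 must be >= 0")
    num <- 0.408 * delta * (rn - g) +
      gamma * (900 / (tmean + 273)) * u2 * (es - ea)
    pmax(num / (delta + gamma * (1 + 0.34 * u2)), 0)
  })
}

#' Irrigation plan for one season
#'
#' Bundles the daily reference ET series, the crop coefficient (a scalar
#' or a per-day vector tracking growth stages), the deficit factor
#' applied to the full requirement (1.00, 0.75 or 0.50 of estimated crop
#' ET), and the stage-timed application events.
#'
#' @param eto daily reference evapotranspiration (mm day-1)
#' @param kc crop coefficient, scalar or per-day, > 0
#' @param deficitFactor fraction of full crop ET applied, in (0, 1]
#' @param events irrigation application amounts (mm), e.g. the eight
#'   stage-timed events plus the sowing application
#' @return an object of class \code{IrrigationPlan}
#' @export
irrigationPlan <- function(eto, kc = 1, deficitFactor = 1,
                           events = numeric()) {
  if (any(eto < 0)) stop("eto must be >= 0")
  if (any(kc <= 0)) stop("kc must be > 0")
  if (!(length(kc) %in% c(1L, length(eto))))
    stop("kc must be a scalar or one value per day")
  if (!(deficitFactor > 0 && deficitFactor <= 1))
    stop("deficitFactor must be in (0, 1]")
  if (any(events < 0)) stop("event amounts must be >= 0")
  structure(list(eto = eto, kc = kc, deficitFactor = deficitFactor,
                 events = events), class = "IrrigationPlan")
}

#' Seasonal crop evapotranspiration of an irrigation plan
#'
#' Sum of daily ETo times Kc over the season, scaled by the deficit
#' factor: the 0.75 and 0.50 plans receive exactly 75 and 50 percent of
#' the full plan's water.
#'
#' @param plan an \code{\link{irrigationPlan}}
#' @return seasonal ETc (mm)
#' @export
seasonalEtc <- function(plan) {
  stopifnot(inherits(plan, "IrrigationPlan"))
  sum(plan$eto * plan$kc) * plan$deficitFactor
}

#' Seasonal actual crop ET from the water balance
#'
#' General water-balance accounting
#' \deqn{ET = ETc + P + Cr - R - D + \Delta S}
#' where ETc is the irrigation water applied (mm), P effective
#' precipitation, Cr capillary rise (zero at the deep-groundwater site),
#' R surface runoff (zero under diked surface irrigation), D deep
#' percolation below the root zone, and Delta S the soil-water storage
#' change, signed as storage(sowing) - storage(harvest) so that a
#' depleted profile adds to seasonal ET.
#'
#' @param etc irrigation water applied (mm)
#' @param p effective precipitation (mm)
#' @param cr capillary rise (mm)
#' @param r surface runoff (mm)
#' @param d deep percolation (mm)
#' @param deltaS storage at sowing minus storage at harvest (mm)
#' @return seasonal actual ET (mm)
#' @export
seasonalEt <- function(etc, p = 0, cr = 0, r = 0, d = 0, deltaS = 0) {
  et <- etc + p + cr - r - d + deltaS
  if (any(et <= 0)) stop("water balance yields non-positive ET")
  et
}

#' Soil profile hydraulic description
#'
#' @param fieldCapacity volumetric water content at field capacity
#'   (m3 m-3)
#' @param wiltingPoint volumetric content at permanent wilting point
#' @param bulkDensity bulk density (g cm-3)
#' @param depth profile depth (m)
#' @return an object of class \code{SoilProfile}. Defaults are the sandy
#'   loam of the reference site: FC 0.151, PWP 0.054, bulk density 1.49,
#'   0.9 m root-zone depth.
#' @export
soilProfile <- function(fieldCapacity = 0.151, wiltingPoint = 0.054,
                        bulkDensity = 1.49, depth = 0.9) {
  if (!(wiltingPoint > 0 && wiltingPoint < fieldCapacity &&
        fieldCapacity < 0.6))
    stop("need 0 < wiltingPoint < fieldCapacity < 0.6")
  if (depth <= 0) stop("depth must be > 0")
  if (bulkDensity <= 0) stop("bulkDensity must be > 0")
  structure(list(fieldCapacity = fieldCapacity,
                 wiltingPoint = wiltingPoint, bulkDensity = bulkDensity,
                 depth = depth), class = "SoilProfile")
}

#' Soil water storage in millimetres
#'
#' Converts a measured water content over a soil profile into a water
#' depth. Gravimetric contents (g water per g soil) are multiplied by
#' bulk density and profile depth; volumetric contents (m3 m-3) by the
#' depth alone. A metre of water depth is 1000 mm.
#'
#' @param content water content, >= 0
#' @param soil a \code{\link{soilProfile}}
#' @param basis \code{"gravimetric"} or \code{"volumetric"}
#' @return stored water (mm)
#' @examples
#' soilWaterStorage(0.10, soilProfile())             # 134.1 mm
#' soilWaterStorage(0.151, soilProfile(), "volumetric") # 135.9 mm capacity
#' @export
soilWaterStorage <- function(content, soil,
                             basis = c("gravimetric", "volumetric")) {
  basis <- match.arg(basis)
  stopifnot(inherits(soil, "SoilProfile"))
  if (any(content < 0)) stop("content must be >= 0")
  if (basis == "gravimetric")
    content * soil$bulkDensity * soil$depth * 1000
  else
    content * soil$depth * 1000
}

#' Deep percolation of an irrigation event
#'
#' Capacity-overflow rule: water draining below the root zone is the
#' excess of pre-irrigation storage plus applied water over the profile's
#' field-capacity storage, floored at zero.
#'
#' @param preStorage soil water storage before the event (mm)
#' @param applied water applied by the event (mm)
#' @param soil a \code{\link{soilProfile}}
#' @return deep percolation (mm)
#' @export
deepPercolation <- function(preStorage, applied, soil) {
  cap <- soilWaterStorage(soil$fieldCapacity, soil, "volumetric")
  pmax(0, preStorage + applied - cap)
}

#' Yield response factor for one treatment combination
#'
#' ky relates the relative yield decrease to the relative seasonal ET
#' deficit of a deficit-irrigated treatment against its fully irrigated
#' reference: ky = (1 - GYa/GYm) / (1 - ETa/ETm). Values below one
#' indicate tolerance to deficit irrigation. Reports round ky to two
#' decimals; the full-precision value is kept.
#'
#' @param eta,etm actual and maximum (full-irrigation) seasonal ET (mm),
#'   with 0 < eta < etm
#' @param gya,gym actual and maximum grain yield, gym > 0
#' @return list with \code{deficit} (1 - ETa/ETm), \code{decrease}
#'   (1 - GYa/GYm), \code{ky}, \code{kyRounded}, \code{defined}
#' @export
kySingle <- function(eta, etm, gya, gym) {
  if (!(etm > 0) || !(gym > 0)) stop("etm and gym must be > 0")
  if (!(eta > 0)) stop("eta must be > 0")
  if (eta > etm) stop("eta must be <= etm")
  kyFromRelative(1 - eta / etm, 1 - gya / gym)
}

#' Yield response factor from relative terms
#'
#' Same statistic as \code{\link{kySingle}} computed directly from the
#' relative ET deficit and relative yield decrease, as tabulated in
#' published deficit-irrigation reports.
#'
#' @param deficit relative seasonal ET deficit, 1 - ETa/ETm, in [0, 1)
#' @param decrease relative yield decrease, 1 - GYa/GYm
#' @return list as in \code{\link{kySingle}}; a zero deficit gives an
#'   undefined-flagged record
#' @export
kyFromRelative <- function(deficit, decrease) {
  if (deficit < 0 || deficit >= 1) stop("deficit must be in [0, 1)")
  if (deficit == 0)
    return(list(deficit = deficit, decrease = decrease, ky = NA_real_,
                kyRounded = NA_real_, defined = FALSE))
  ky <- decrease / deficit
  list(deficit = deficit, decrease = decrease, ky = ky,
       kyRounded = round(ky, 2), defined = TRUE)
}

#' Pooled yield response factor
#'
#' Slope of the relation between relative yield decrease and relative ET
#' deficit over many treatment records. The default regression is
#' through the origin (slope = sum(xy)/sum(x^2)), as the response-factor
#' formulation ties a zero deficit to a zero decrease; a free-intercept
#' fit is available for comparison with plotted seasonal regressions.
#'
#' @param deficit vector of relative ET deficits
#' @param decrease vector of relative yield decreases
#' @param method \code{"through_origin"} (default) or
#'   \code{"free_intercept"}
#' @return the pooled ky (slope)
#' @export
kyPooled <- function(deficit, decrease,
                     method = c("through_origin", "free_intercept")) {
  method <- match.arg(method)
  if (length(deficit) != length(decrease))
    stop("deficit and decrease must have equal length")
  if (length(deficit) < 1) stop("need at least one record")
  if (all(deficit == 0)) stop("all deficits are zero")
  if (method == "through_origin")
    sum(deficit * decrease) / sum(deficit^2)
  else {
    if (length(deficit) < 2) stop("free_intercept needs >= 2 records")
    unname(coef(lm(decrease ~ deficit))[2])
  }
}

#' Water use efficiency
#'
#' Grain yield per unit of seasonal actual crop evapotranspiration.
#'
#' @param gy grain yield (g m-2)
#' @param et seasonal actual ET (mm)
#' @return WUE (g m-2 mm-1)
#' @export
wue <- function(gy, et) {
  if (any(et <= 0)) stop("et must be > 0")
  gy / et
}

#' Published per-treatment ky inputs
#'
#' The relative seasonal ET deficits and relative grain-yield decreases
#' of the two deficit irrigation rates (0.75 and 0.50 of crop ET)
#' crossed with five plant densities in two growing seasons, together
#' with the ky value printed alongside them in the source report. These
#' are inputs for \code{\link{kyFromRelative}}; recomputing
#' decrease/deficit reproduces the printed ky to +/- 0.005 in 15 of the
#' 20 cells, the rest differing through the 3-decimal rounding of the
#' printed ratio terms (one cell, season 2 / 0.75 rate / 450 seeds m-2,
#' is a gross misprint: the ratio gives 1.23 against a printed 1.13).
#'
#' @return data.frame: season, irrigation, density, rel_et_deficit,
#'   rel_gy_decrease, ky_printed
#' @export
publishedKyInputs <- function() {
  path <- system.file("extdata", "published_ky_inputs.csv",
                      package = "specyield", mustWork = TRUE)
  read.csv(path)
}
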