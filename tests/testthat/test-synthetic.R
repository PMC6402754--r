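test_that("equal config and seed give bit-identical experiments", {
  cfg <- syntheticConfig(seed = 42)
  a <- generateExperiment(cfg)
  b <- generateExperiment(cfg)
  expect_identical(reflectance(a$spectra), reflectance(b$spectra))
  expect_identical(a$agronomy, b$agronomy)
  expect_identical(a$water, b$water)
  expect_identical(a$signal, b$signal)
})

test_that("invalid config fields are reported by name", {
  expect_error(syntheticConfig(replicates = 0), "replicates")
  expect_error(syntheticConfig(densities = c(350, 250)), "densities")
  expect_error(syntheticConfig(spectralNoiseSd = -1), "spectralNoiseSd")
  expect_error(syntheticConfig(irrigationRates = c(1, 1.5)),
               "irrigationRates")
})

test_that("design layout is one record per season x rate x density x rep", {
  k <- sampleKeys(refExperiment$spectra)
  expect_equal(nrow(k), 2 * 3 * 5 * 3)
  expect_equal(nrow(unique(k)), nrow(k))
  expect_equal(sort(unique(k$density)), c(150, 250, 350, 450, 550))
  expect_equal(sort(unique(k$irrigation)), c(0.50, 0.75, 1.00))
})

test_that("generated reflectance stays within [0, 1]", {
  r <- reflectance(refExperiment$spectra)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("WUE equals GY / seasonal ET to machine precision everywhere", {
  a <- refExperiment$agronomy
  expect_identical(a$WUE, a$GY / a$ET)
  w <- refExperiment$water
  expect_equal(w$et,
               seasonalEt(w$etc, p = w$p, cr = w$cr, r = w$runoff,
                          d = w$d, deltaS = w$deltaS))
})

test_that("noise-free surface orders yield by irrigation at fixed density", {
  exp <- generateExperiment(noiselessConfig())
  a <- exp$agronomy
  for (s in unique(a$season)) for (d in unique(a$density)) {
    hi <- a$GY[a$season == s & a$density == d & a$irrigation == 1.00]
    mid <- a$GY[a$season == s & a$density == d & a$irrigation == 0.75]
    lo <- a$GY[a$season == s & a$density == d & a$irrigation == 0.50]
    expect_true(all(hi > mid) && all(mid > lo))
    # Spearman correlation between rate and yield is exactly +1
    cell <- a[a$season == s & a$density == d & a$replicate == 1, ]
    expect_equal(cor(cell$irrigation, cell$GY, method = "spearman"), 1)
  }
  expect_true(all(a$TDW[a$irrigation == 1.00] >
                  a$TDW[a$irrigation == 0.50]))
})

test_that("optimum density does not increase as irrigation decreases", {
  # noise-free: the argmax over density is the surface optimum itself
  a <- generateExperiment(noiselessConfig())$agronomy
  m <- aggregate(GY ~ irrigation + density, a, mean)
  optAt <- function(w) {
    sub <- m[m$irrigation == w, ]
    sub$density[which.max(sub$GY)]
  }
  expect_true(optAt(0.50) <= optAt(0.75))
  expect_true(optAt(0.75) <= optAt(1.00))
  # Monte-Carlo with noise: mean optimum under deficit stays at or below
  # the full-irrigation optimum
  opts <- vapply(1:20, function(seed) {
    a <- generateExperiment(syntheticConfig(seed = seed))$agronomy
    m <- aggregate(GY ~ irrigation + density, a, mean)
    c(full = m$density[m$irrigation == 1.00][
        which.max(m$GY[m$irrigation == 1.00])],
      deficit = m$density[m$irrigation == 0.50][
        which.max(m$GY[m$irrigation == 0.50])])
  }, c(full = 0, deficit = 0))
  expect_lte(mean(opts["deficit", ]), mean(opts["full", ]))
})

test_that("subsetting the design does not change generated values", {
  full <- generateExperiment(syntheticConfig(seed = 5))
  one <- generateExperiment(syntheticConfig(seed = 5, seasons = 1L))
  k <- sampleKeys(full$spectra)$season == 1
  expect_identical(reflectance(full$spectra)[, k],
                   reflectance(one$spectra))
})

test_that("canopy spectrum honours the mixture identity and monotonicity", {
  g <- WavelengthGrid()
  wl <- wavelengths(g)
  bare <- latentPlotState(0, 0, 0, 0)
  expect_identical(canopySpectrum(bare, g), soilEndmember(wl))
  dry <- latentPlotState(0.9, 3, 0.8, 0.2)
  wet <- latentPlotState(0.9, 3, 0.8, 0.8)
  expect_lt(canopySpectrum(wet, g)[wl == 1450],
            canopySpectrum(dry, g)[wl == 1450])
  sparse <- latentPlotState(0.6, 1, 0.8, 0.5)
  dense <- latentPlotState(0.6, 4, 0.8, 0.5)
  ndvi <- function(s) normalizedDifference(s, 900, 685, g)
  expect_gt(ndvi(canopySpectrum(dense, g)), ndvi(canopySpectrum(sparse, g)))
  expect_error(latentPlotState(1.2, 1, 1, 1), "cover")
})

test_that("met series is deterministic, bounded, and matches climate normals", {
  m1 <- generateMetSeries(150, seed = 9)
  m2 <- generateMetSeries(150, seed = 9)
  expect_identical(m1, m2)
  expect_true(all(m1$tmax > m1$tmin))
  expect_true(all(m1$rh > 0 & m1$rh < 100))
  expect_true(all(m1$u2 > 0))
  expect_true(all(m1$rn >= 0))
  expect_true(all(m1$es >= m1$ea))
  dec <- m1$month == 12
  expect_lt(abs(mean(m1$tmean[dec]) - 16.4), 1.5)
  expect_error(generateMetSeries(0), "days")
})
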