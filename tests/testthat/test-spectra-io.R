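test_that("write + read round-trips a dataset bit-identically", {
  ds <- refExperiment$spectra[, 1:6]
  ds <- SpectralDataset(unname(reflectance(ds)), datasetGrid(ds),
                        sampleKeys(ds))
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(ds, path)
  back <- readSpectra(path)
  expect_identical(reflectance(back)[, colnames(reflectance(ds))],
                   reflectance(ds))
  expect_equal(wavelengths(back), wavelengths(ds))
  expect_identical(sort(colnames(reflectance(back))),
                   sort(sampleKeyString(sampleKeys(ds))))
})

test_that("repeated write of the same dataset is bit-identical", {
  ds <- refExperiment$spectra[, 1:4]
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(ds, p1); writeSpectra(ds, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("malformed files are rejected with located errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,S1_I1.00_D150_R1,S1_I1.00_D150_R1",
               "400,0.1,0.2", "401,0.1,0.2"), p)
  expect_error(readSpectra(p), "S1_I1.00_D150_R1")
  writeLines(c("wl,S1_I1.00_D150_R1", "400,0.1"), p)
  expect_error(readSpectra(p), "wavelength_nm")
  writeLines(c("wavelength_nm,S1_I1.00_D150_R1", "400,abc", "401,0.2"), p)
  expect_error(readSpectra(p), "non-numeric")
  writeLines(c("wavelength_nm,S1_I1.00_D150_R1", "400,-0.1", "401,0.2"), p)
  expect_error(readSpectra(p), "negative")
  writeLines(c("wavelength_nm,S1_I1.00_D150_R1", "400,0.1", "402,0.2",
               "403,0.3"), p)
  expect_error(readSpectra(p), "regular")
})

test_that("the xlsx dialect reads the same dataset as the csv dialect", {
  ds <- refExperiment$spectra[, 1:3]
  csv <- withr::local_tempfile(fileext = ".csv")
  xlsx <- withr::local_tempfile(fileext = ".xlsx")
  writeSpectra(ds, csv)
  cmd <- sprintf(
    "import pandas as pd; pd.read_csv(%s).to_excel(%s, index=False)",
    shQuote(csv), shQuote(xlsx))
  status <- system2("python", c("-c", shQuote(cmd)))
  expect_identical(status, 0L)
  a <- readSpectra(csv)
  b <- readSpectra(xlsx, dialect = "xlsx")
  expect_equal(reflectance(b), reflectance(a), tolerance = 1e-12)
  expect_identical(sampleKeys(b), sampleKeys(a))
})

test_that("white-reference calibration divides bandwise and names bad bands", {
  g <- WavelengthGrid(1398, 1402, 1)
  expect_equal(calibrateReflectance(rep(0.3, 5), rep(0.3, 5)), rep(1, 5))
  expect_equal(calibrateReflectance(0.05, 0.10), 0.5)
  ref <- c(0.2, 0.2, 0, 0.2, 0.2)
  expect_error(calibrateReflectance(rep(0.1, 5), ref, g), "1400 nm")
  expect_error(calibrateReflectance(1:3, 1:4), "equal length")
})

test_that("averaging spectra is the bandwise mean and reduces variance", {
  s <- runif(10)
  expect_equal(averageSpectra(list(s)), s)
  expect_equal(averageSpectra(list(rep(0.2, 4), rep(0.4, 4))), rep(0.3, 4))
  expect_error(averageSpectra(list(1:3, 1:4)), "mismatch")
  g <- WavelengthGrid()
  st <- latentPlotState(0.8, 3, 0.9, 0.6)
  reps <- lapply(1:6, function(i) canopySpectrum(st, g, 0.05, seed = i))
  clean <- canopySpectrum(st, g)
  avg <- averageSpectra(reps)
  perScan <- mean(vapply(reps, function(r) mean((r - clean)^2), 0))
  expect_lt(mean((avg - clean)^2), perScan)
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  src <- WavelengthGrid(1000, 1002, 2)
  tgt <- WavelengthGrid(1000, 1002, 1)
  expect_equal(resampleToGrid(c(0.2, 0.4), src, tgt), c(0.2, 0.3, 0.4))
  same <- WavelengthGrid(500, 510, 1)
  v <- runif(11)
  expect_equal(resampleToGrid(v, same, same), v)
  # idempotent on its own output grid
  out <- resampleToGrid(c(0.2, 0.4), src, tgt)
  expect_equal(resampleToGrid(out, tgt, tgt), out)
  expect_error(resampleToGrid(rep(0.1, 2151), WavelengthGrid(),
                              WavelengthGrid(340, 500, 1)),
               "extrapolation")
})

test_that("index definitions and synthetic configs round-trip through YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- name: NDI_1450_900",
               "  kind: normalized_difference",
               "  bands: [1450, 900]",
               "- name: MYOSAVI",
               "  kind: osavi",
               "  bands: [800, 670]",
               "  constants: [0.16]"), p)
  defs <- readIndexDefinitions(p)
  expect_length(defs, 2)
  g <- WavelengthGrid()
  s <- runif(nBands(g), 0.05, 0.6)
  expect_equal(computeIndex(s, defs$NDI_1450_900, g),
               normalizedDifference(s, 1450, 900, g))
  expect_equal(computeIndex(s, defs$MYOSAVI, g),
               computeIndex(s, builtinDefinitions()$OSAVI, g))
  writeLines("- name: X\n  kind: osavi", p)
  expect_error(readIndexDefinitions(p), "bands")

  cfgPath <- withr::local_tempfile(fileext = ".yaml")
  cfg <- syntheticConfig(seed = 77, replicates = 2L)
  writeSyntheticConfig(cfg, cfgPath)
  back <- readSyntheticConfig(cfgPath)
  expect_equal(back, cfg)
  expect_identical(generateExperiment(back)$agronomy,
                   generateExperiment(cfg)$agronomy)
})
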