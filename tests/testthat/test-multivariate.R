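threeFactorData <- function(n = 30, p = 120, seed = 42) {
  set.seed(seed)
  T3 <- matrix(rnorm(n * 3), n, 3)
  P3 <- matrix(rnorm(p * 3), p, 3)
  list(X = T3 %*% t(P3), y = as.vector(T3 %*% c(1, -2, 0.5)))
}

test_that("noise-free low-rank data needs no more factors than its rank", {
  d <- threeFactorData()
  m <- fitCalibration(d$X, d$y, "plsr")
  expect_lte(m@setting$ncomp, 3)
  expect_gte(cor(d$y, m@fitted)^2, 0.999)
  expect_equal(min(m@candidates$rmsecv),
               m@candidates$rmsecv[m@candidates$ncomp == m@setting$ncomp])
})

test_that("model fitting is deterministic and validation never refits", {
  d <- threeFactorData(seed = 7)
  m1 <- fitCalibration(d$X, d$y, "plsr")
  m2 <- fitCalibration(d$X, d$y, "plsr")
  expect_identical(m1@setting, m2@setting)
  expect_identical(m1@coefficients, m2@coefficients)
  expect_equal(predictCalibration(m1, d$X), m1@fitted, tolerance = 1e-8)
  s1 <- fitCalibration(d$X, d$y + rnorm(30), "svr")
  expect_equal(predictCalibration(s1, d$X), s1@fitted, tolerance = 1e-8)
})

test_that("duplicating every sample leaves the fitted path unchanged", {
  d <- threeFactorData(seed = 3)
  k <- 3
  a <- specyield:::pls1Paths(d$X, d$y, k)
  b <- specyield:::pls1Paths(rbind(d$X, d$X), c(d$y, d$y), k)
  expect_equal(a$B[, k], b$B[, k], tolerance = 1e-8)
  expect_equal(a$intercepts[k], b$intercepts[k], tolerance = 1e-8)
})

test_that("pure-noise responses are not cross-validated into signal", {
  r2 <- vapply(1:9, function(seed) {
    set.seed(seed)
    sel <- sample(ncol(refExperiment$spectra), 30)
    X <- t(reflectance(refExperiment$spectra)[, sel])
    y <- rnorm(30)
    m <- fitCalibration(X, y, "plsr")
    cor(y, m@cvPred)^2
  }, 0)
  expect_lte(median(r2), 0.2)
})

test_that("the PLS path agrees with an independent PLS implementation", {
  set.seed(12)
  n <- 24; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  y <- as.vector(X[, 1:5] %*% runif(5)) + rnorm(n, 0, 0.1)
  k <- 4
  colnames(X) <- paste0("V", seq_len(p))
  mine <- specyield:::pls1Paths(X, y, k)
  ref <- mixOmics::pls(X, y, ncomp = k, mode = "regression",
                       scale = FALSE)
  pred <- predict(ref, X)$predict[, 1, k]
  minePred <- as.vector(X %*% mine$B[, k]) + mine$intercepts[k]
  expect_equal(minePred, unname(pred), tolerance = 1e-8)
})

test_that("validation reports carry the adjusted R2 and line summaries", {
  # a synthetic model whose prediction is the single predictor itself
  fake <- new("SpectralCalibration", method = "plsr", trait = "t",
              wavelengths = 1, centerX = TRUE, centerY = TRUE,
              setting = list(ncomp = 1),
              candidates = data.frame(ncomp = 1, rmsecv = 0),
              coefficients = 1, intercept = 0, xMean = 0, yMean = 0,
              projection = matrix(1, 1, 1), svrModel = NULL,
              fitted = 0, cvPred = 0, y = 0)
  y <- rnorm(10)
  perfect <- validateCalibration(fake, matrix(y, ncol = 1), y)
  expect_equal(perfect$adj_r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0)
  # an exact R2 = 0.9 construction: adjusted R2 = 0.8875 at n = 10
  set.seed(5)
  x <- seq_len(10)
  e <- resid(lm(rnorm(10) ~ x))
  xc <- (x - mean(x)) / sd(x)
  pred <- sqrt(0.9) * xc + sqrt(0.1) * e / sd(e)
  rep <- validateCalibration(fake, matrix(pred, ncol = 1), x)
  expect_equal(rep$r2, 0.9, tolerance = 1e-12)
  expect_equal(rep$adj_r2, 0.8875, tolerance = 1e-12)
  expect_true(rep$obs_min <= min(x) && rep$obs_max >= max(x))
  expect_error(predictCalibration(fake, matrix(1, 1, 3)), "mismatch")
})

test_that("subset validation covers rates, densities and seasons once each", {
  ds <- refExperiment$spectra
  y <- refExperiment$agronomy$GY
  X <- t(reflectance(ds))
  m <- fitCalibration(X, y, "plsr", wavelengths = wavelengths(ds))
  suite <- subsetValidationSuite(m, ds, y)
  expect_equal(nrow(suite), 3 + 5 + 2)
  expect_equal(as.vector(table(suite$subset)[c("irrigation", "density",
                                               "season")]),
               c(3L, 5L, 2L))
  keys <- sampleKeys(ds)
  sel <- keys$irrigation == 0.75
  manual <- validateCalibration(m, X[sel, ], y[sel], label = "I0.75")
  expect_equal(suite[suite$label == "I0.75", -1], manual,
               ignore_attr = TRUE)
})

test_that("per-rate validation of a planted-signal trait is mostly significant", {
  hits <- unlist(lapply(1:10, function(seed) {
    exp <- generateExperiment(syntheticConfig(seed = seed))
    X <- t(reflectance(exp$spectra))
    y <- exp$agronomy$GY
    m <- fitCalibration(X, y, "plsr")
    suite <- subsetValidationSuite(m, exp$spectra, y)
    suite$p[suite$subset == "irrigation"] <= 0.05
  }))
  expect_gte(mean(hits), 0.8)
})

test_that("degenerate calibration inputs are refused", {
  d <- threeFactorData()
  expect_error(fitCalibration(d$X, rep(1, 30), "plsr"), "constant")
  expect_error(fitCalibration(d$X[1:4, ], d$y[1:4], "plsr"), "at least 6")
  expect_error(fitCalibration(d$X, d$y[-1], "plsr"), "length")
})
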