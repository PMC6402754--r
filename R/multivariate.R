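# PLS1 regression via NIPALS on a (possibly reduced) predictor matrix.
# Returns coefficient vectors and intercepts for 1..K components.
# X: n x p (uncentered), y: length n. Centering is done here.
pls1Paths <- function(X, y, K, centerX = TRUE, centerY = TRUE) {
  n <- nrow(X); p <- ncol(X)
  xm <- if (centerX) colMeans(X) else rep(0, p)
  ym <- if (centerY) mean(y) else 0
  E <- sweep(X, 2, xm)
  f <- y - ym
  W <- matrix(0, p, K); P <- matrix(0, p, K); Q <- numeric(K)
  B <- matrix(0, p, K)
  nw1 <- tt1 <- NA_real_
  for (k in seq_len(K)) {
    w <- crossprod(E, f)                      # p x 1
    nw <- sqrt(sum(w^2))
    if (k == 1) nw1 <- nw
    # residual covariance (or score scale) exhausted: rank reached
    if (nw <= 1e-10 * max(nw1, .Machine$double.xmin)) { K <- k - 1L; break }
    w <- w / nw
    t <- as.vector(E %*% w)
    tt <- sum(t^2)
    if (k == 1) tt1 <- tt
    if (tt <= 1e-20 * max(tt1, .Machine$double.xmin)) { K <- k - 1L; break }
    pl <- as.vector(crossprod(E, t)) / tt
    q <- sum(f * t) / tt
    E <- E - tcrossprod(t, pl)
    f <- f - q * t
    W[, k] <- w; P[, k] <- pl; Q[k] <- q
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    B[, k] <- Wk %*% solve(crossprod(Pk, Wk), Q[seq_len(k)])
  }
  if (K < 1) stop("no usable latent factors (degenerate predictors)")
  B <- B[, seq_len(K), drop = FALSE]
  list(B = B, intercepts = ym - as.vector(crossprod(B, xm)), K = K,
       xMean = xm, yMean = ym)
}

# leave-one-out RMSECV over latent-factor counts 1..K
plsLoocv <- function(Z, y, K, centerX, centerY) {
  n <- nrow(Z)
  err <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    fit <- pls1Paths(Z[-i, , drop = FALSE], y[-i], K, centerX, centerY)
    pred <- as.vector(Z[i, ] %*% fit$B) + fit$intercepts
    err[i, seq_len(fit$K)] <- pred - y[i]
  }
  sqrt(colMeans(err^2))
}

defaultSvrGrid <- function(y)
  expand.grid(kernel = "linear", cost = c(0.1, 1, 10, 100),
              epsilon = 0.1, gamma = NA_real_,
              stringsAsFactors = FALSE)

svrLoocv <- function(Z, y, grid) {
  n <- nrow(Z)
  rmse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    err <- numeric(n)
    for (i in seq_len(n)) {
      m <- svrFitOne(Z[-i, , drop = FALSE], y[-i], grid[g, ])
      err[i] <- predict(m, Z[i, , drop = FALSE]) - y[i]
    }
    rmse[g] <- sqrt(mean(err^2))
  }
  rmse
}

svrFitOne <- function(Z, y, setting) {
  args <- list(x = Z, y = y, type = "eps-regression",
               kernel = setting$kernel, cost = setting$cost,
               epsilon = setting$epsilon, scale = FALSE)
  if (setting$kernel == "radial" && is.finite(setting$gamma))
    args$gamma <- setting$gamma
  do.call(e1071::svm, args)
}

#' Fit a full-spectrum calibration model
#'
#' Calibrates one agronomic trait on full-spectrum reflectance with
#' either partial least squares regression (PLSR) or epsilon-insensitive
#' support vector regression (SVR). Candidate settings -- latent-factor
#' counts 1..\code{maxFactors} for PLSR, a small hyperparameter grid for
#' SVR (linear kernel by default, conservative for n << p spectra) --
#' are scored by leave-one-out cross-validated RMSE over the whole
#' calibration set, and the setting with the lowest RMSECV is selected
#' (ties within numerical tolerance go to the simpler setting). The
#' only default preprocessing is mean-centering of predictors and
#' response.
#'
#' Internally the spectra are rotated into their row space with a
#' singular value decomposition before cross-validation; with mean
#' centering and linear models this is exact (the fits and predictions
#' are identical to working in the full band space) and makes
#' leave-one-out over thousands of bands cheap.
#'
#' @param X n x p matrix of spectra (rows = samples) on the full grid
#' @param y trait values, length n >= 6, non-constant
#' @param method \code{"plsr"} or \code{"svr"}
#' @param wavelengths band axis of X (nm), for provenance checks
#' @param maxFactors candidate latent-factor cap, default
#'   min(20, n - 2)
#' @param center mean-center predictors and response
#' @param svrGrid data.frame of SVR candidate settings (kernel, cost,
#'   epsilon, gamma); epsilon is taken as a fraction of sd(y)
#' @return a \linkS4class{SpectralCalibration}
#' @export
fitCalibration <- function(X, y, method = c("plsr", "svr"),
                           wavelengths = seq_len(ncol(X)),
                           maxFactors = NULL, center = TRUE,
                           svrGrid = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y length differs from nrow(X)")
  if (n < 6) stop("need at least 6 samples, got ", n)
  if (sd(y) == 0) stop("degenerate response: y is constant")
  if (length(wavelengths) != ncol(X))
    stop("wavelengths length differs from ncol(X)")
  # exact row-space reduction: Z = X V, predictions unchanged
  sv <- svd(X, nu = 0, nv = min(n, ncol(X)))
  r <- sum(sv$d > max(sv$d) * 1e-12)
  V <- sv$v[, seq_len(r), drop = FALSE]
  Z <- X %*% V
  tol <- 1e-8 * sd(y)
  if (method == "plsr") {
    K <- if (is.null(maxFactors)) min(20L, n - 2L) else
      min(as.integer(maxFactors), n - 2L, r)
    rmsecv <- plsLoocv(Z, y, K, center, center)
    usable <- which(is.finite(rmsecv))
    best <- min(rmsecv[usable])
    ncomp <- min(usable[rmsecv[usable] <= best + tol])
    fit <- pls1Paths(Z, y, ncomp, center, center)
    bz <- fit$B[, fit$K]
    coefB <- as.vector(V %*% bz)
    intercept <- fit$intercepts[fit$K]
    fitted <- as.vector(Z %*% bz) + intercept
    cvPred <- loocvPredictions(Z, y, function(Zt, yt, Zv)
      { f <- pls1Paths(Zt, yt, min(ncomp, nrow(Zt) - 1L), center, center)
        as.vector(Zv %*% f$B[, f$K]) + f$intercepts[f$K] })
    candidates <- data.frame(ncomp = seq_along(rmsecv),
                             rmsecv = rmsecv)[usable, , drop = FALSE]
    setting <- list(ncomp = ncomp)
    svrModel <- NULL
  } else {
    grid <- if (is.null(svrGrid)) defaultSvrGrid(y) else svrGrid
    grid$epsilon <- grid$epsilon * sd(y)
    rmsecv <- svrLoocv(Z, y, grid)
    best <- min(rmsecv)
    g <- which(rmsecv <= best + tol)[1]
    setting <- as.list(grid[g, ])
    svrModel <- svrFitOne(Z, y, grid[g, ])
    fitted <- as.vector(predict(svrModel, Z))
    cvPred <- loocvPredictions(Z, y, function(Zt, yt, Zv)
      as.vector(predict(svrFitOne(Zt, yt, grid[g, ]), Zv)))
    candidates <- cbind(grid, rmsecv = rmsecv)
    coefB <- numeric(0)
    intercept <- NA_real_
  }
  new("SpectralCalibration", method = method, trait = "trait",
      wavelengths = as.numeric(wavelengths), centerX = center,
      centerY = center, setting = setting, candidates = candidates,
      coefficients = coefB, intercept = intercept,
      xMean = colMeans(X), yMean = mean(y), projection = V,
      svrModel = svrModel, fitted = fitted, cvPred = cvPred, y = y)
}

loocvPredictions <- function(Z, y, fitPredict) {
  n <- nrow(Z)
  vapply(seq_len(n), function(i)
    fitPredict(Z[-i, , drop = FALSE], y[-i], Z[i, , drop = FALSE]), 0)
}

#' Predict from a fitted calibration
#'
#' Applies the frozen calibration model to new spectra; no refitting
#' happens, so predictions on the calibration set equal the stored
#' fitted values.
#'
#' @param model a \linkS4class{SpectralCalibration}
#' @param X new spectra, bands matching the calibration grid
#' @return predicted trait values
#' @export
predictCalibration <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model@wavelengths))
    stop("band grid mismatch: model has ", length(model@wavelengths),
         " bands, X has ", ncol(X))
  if (model@method == "plsr")
    as.vector(X %*% model@coefficients) + model@intercept
  else
    as.vector(predict(model@svrModel, X %*% model@projection))
}

#' Validate a calibration on a data subset
#'
#' Scores frozen-model predictions on a validation subset the way
#' subset tables report them: adjusted R-squared
#' (1 - (1 - R2)(n - 1)/(n - 2) for the single observed-vs-predicted
#' regressor), RMSE, the slope and intercept of the
#' predicted-versus-observed line, the p-value of that regression, and
#' the observed and predicted ranges.
#'
#' @param model a \linkS4class{SpectralCalibration}
#' @param X spectra of the subset
#' @param y observed trait values
#' @param label optional subset label carried into the report
#' @return one-row data.frame: label, n, r2, adj_r2, rmse, slope,
#'   intercept, p, obs_min, obs_max, pred_min, pred_max
#' @export
validateCalibration <- function(model, X, y, label = "subset") {
  if (!length(y)) stop("empty validation subset")
  pred <- predictCalibration(model, X)
  n <- length(y)
  rmse <- sqrt(mean((y - pred)^2))
  if (n >= 3 && sd(y) > 0 && sd(pred) > 0) {
    f <- simpleLinearFit(y, pred)
    r2 <- f$r2
    adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else NA_real_
    slope <- f$slope; intercept <- f$intercept; p <- f$p
  } else {
    r2 <- adj <- slope <- intercept <- p <- NA_real_
    if (isTRUE(all.equal(pred, y))) { r2 <- 1; adj <- 1 }
  }
  if (rmse == 0) { r2 <- 1; adj <- 1; slope <- 1; intercept <- 0; p <- 0 }
  data.frame(label = label, n = n, r2 = r2, adj_r2 = adj, rmse = rmse,
             slope = slope, intercept = intercept, p = p,
             obs_min = min(y), obs_max = max(y), pred_min = min(pred),
             pred_max = max(pred))
}

#' Subset validation reports across the design
#'
#' Applies \code{\link{validateCalibration}} to the canonical reporting
#' subsets of the crossed design: one report per irrigation rate, per
#' plant density and per season (3 + 5 + 2 = 10 on the reference
#' design).
#'
#' @param model a \linkS4class{SpectralCalibration}
#' @param dataset the \linkS4class{SpectralDataset} carrying the keys
#' @param y observed trait values aligned to the dataset samples
#' @return data.frame of validation reports, one row per subset, with a
#'   \code{subset} column (\code{irrigation}/\code{density}/
#'   \code{season}) and \code{label}
#' @export
subsetValidationSuite <- function(model, dataset, y) {
  keys <- sampleKeys(dataset)
  X <- t(reflectance(dataset))
  out <- list()
  addReports <- function(field, fmt) {
    for (v in sort(unique(keys[[field]]), decreasing = field == "irrigation")) {
      sel <- keys[[field]] == v
      if (!any(sel)) { warning("empty subgroup ", field, " = ", v); next }
      rep <- validateCalibration(model, X[sel, , drop = FALSE], y[sel],
                                 label = sprintf(fmt, v))
      rep$subset <- field
      out[[length(out) + 1L]] <<- rep
    }
  }
  addReports("irrigation", "I%.2f")
  addReports("density", "D%g")
  addReports("season", "S%g")
  res <- do.call(rbind, out)
  res[, c("subset", setdiff(colnames(res), "subset"))]
}
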