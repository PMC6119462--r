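## Model-performance battery: k-fold CV with full refitting, the metric
## set (RMSE, ME, R2, CCC, rho), z-score calibration, coverage
## (accuracy) tables, CV-residual variogram diagnostics and two-stage
## error-guided sampling.

#' Random (optionally stratified) k-fold assignment
#'
#' Partitions 1..n into k folds whose sizes differ by at most one;
#' deterministic for a fixed seed. With strata, each stratum is split
#' proportionally (per-fold class counts differ from proportionality by
#' at most one).
#'
#' @param n number of observations.
#' @param k number of folds (2 <= k <= n).
#' @param seed RNG seed.
#' @param strata optional labels for stratified assignment.
#' @return Integer fold id per observation.
#' @export
kfoldSplit <- function(n, k, seed = 1L, strata = NULL) {
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= n")
  with_seed(seed, {
    fold <- integer(n)
    if (is.null(strata)) {
      fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
    } else {
      strata <- as.factor(strata)
      start <- 0L
      for (lv in levels(strata)) {
        idx <- which(strata == lv)
        fold[idx[sample.int(length(idx))]] <-
          (start + seq_along(idx) - 1L) %% k + 1L
        start <- start + length(idx)
      }
    }
    fold
  })
}

#' Accuracy metrics of held-out predictions
#'
#' \code{rmse = sqrt(mean((yhat - y)^2))}; \code{me = mean(yhat - y)}
#' (predicted minus observed, so positive ME means over-prediction);
#' \code{r2 = 1 - SSE/SST} with SST about the observed mean of the
#' validation points; \code{rho} the Pearson correlation; and Lin's
#' concordance \code{ccc = 2 rho s_yhat s_y / (s_yhat^2 + s_y^2 +
#' (mu_yhat - mu_y)^2)}, which penalizes both imprecision and bias and
#' never exceeds |rho|.
#'
#' @param yObs,yHat equal-length numeric vectors (>= 2 values).
#' @return list(rmse, me, r2, ccc, rho). When the observations have zero
#'   variance, r2/ccc/rho are NA with a warning.
#' @export
computeMetrics <- function(yObs, yHat) {
  if (length(yObs) != length(yHat)) stop("length mismatch")
  if (length(yObs) < 2L) stop("need at least two values")
  rmse <- sqrt(mean((yHat - yObs)^2))
  me <- mean(yHat - yObs)
  sst <- sum((yObs - mean(yObs))^2)
  if (sst == 0) {
    warning("zero variance in observations; r2/ccc/rho undefined",
            call. = FALSE)
    return(list(rmse = rmse, me = me, r2 = NA_real_, ccc = NA_real_,
                rho = NA_real_))
  }
  sse <- sum((yHat - yObs)^2)
  r2 <- 1 - sse / sst
  rho <- if (stats::sd(yHat) == 0) NA_real_ else stats::cor(yObs, yHat)
  ccc <- 2 * stats::cov(yHat, yObs) /
    (stats::var(yHat) + stats::var(yObs) + (mean(yHat) - mean(yObs))^2)
  list(rmse = rmse, me = me, r2 = r2, ccc = ccc, rho = rho)
}

#' z-score calibration of predicted uncertainties
#'
#' \code{z = (yhat - y) / sigma} per held-out point. Well-calibrated
#' prediction-error SDs give mean(z) near 0 and var(z) near 1; variance
#' substantially below 1 means the model overestimates its actual
#' uncertainty, substantially above 1 means it underestimates it.
#' Points with sigma = 0 are excluded and counted.
#'
#' @param yObs,yHat,sigmaHat equal-length vectors; sigmaHat >= 0.
#' @return list(z_mean, z_var, n_excluded, assessment, z).
#' @export
zscoreStats <- function(yObs, yHat, sigmaHat) {
  if (any(sigmaHat < 0)) stop("sigmaHat must be non-negative")
  excl <- sigmaHat == 0
  if (all(excl)) stop("all predicted error SDs are zero")
  z <- (yHat[!excl] - yObs[!excl]) / sigmaHat[!excl]
  zv <- stats::var(z)
  assessment <- if (is.na(zv)) NA_character_
    else if (zv < 0.5) "uncertainty overestimated (sigma too large)"
    else if (zv > 2) "uncertainty underestimated (sigma too small)"
    else "approximately calibrated"
  list(z_mean = mean(z), z_var = zv, n_excluded = sum(excl),
       assessment = assessment, z = z)
}

#' Empirical coverage of symmetric prediction intervals
#'
#' For each nominal level L, the empirical coverage is the fraction of
#' observations falling inside the central interval
#' \code{[yhat_(1-L)/2, yhat_(1+L)/2]} (symmetric in probability around
#' the median). Plotting empirical against nominal coverage gives the
#' accuracy plot used to judge interval calibration.
#'
#' @param yObs held-out observations.
#' @param quantiles m x q matrix of quantile predictions (or a
#'   \linkS4class{QuantilePrediction}).
#' @param qs probabilities of the quantile columns (taken from the
#'   object when omitted).
#' @param levels nominal levels.
#' @return data.frame(nominal, empirical).
#' @export
coverageTable <- function(yObs, quantiles, qs = NULL,
                          levels = c(seq(0.1, 0.9, 0.1), 0.6827, 0.95)) {
  if (methods::is(quantiles, "QuantilePrediction")) {
    qs <- quantiles@qs
    quantiles <- quantiles@values
  }
  if (is.null(qs)) stop("supply qs for a plain quantile matrix")
  emp <- vapply(levels, function(L) {
    lo <- (1 - L) / 2; hi <- (1 + L) / 2
    i <- which(abs(qs - lo) < 1e-9); j <- which(abs(qs - hi) < 1e-9)
    if (!length(i) || !length(j))
      stop(sprintf("missing quantiles %.5g / %.5g for nominal level %g",
                   lo, hi, L))
    mean(yObs >= quantiles[, i[1]] & yObs <= quantiles[, j[1]])
  }, numeric(1))
  data.frame(nominal = levels, empirical = emp)
}

#' Spatial autocorrelation left in cross-validation residuals
#'
#' Estimates and fits a variogram of the CV residuals and reports a
#' structure fraction: the share of the residual variance that the
#' fitted model accumulates between the median nearest-neighbour
#' distance \code{h_nn} and the maximum observed lag \code{h_max},
#' \code{(gamma(h_max) - gamma(h_nn)) / gamma(h_max)}. Evaluating over
#' the data's own distance span matters in both directions: a fitted
#' range far below the point spacing is observationally nugget, and a
#' fitted "structure" whose correlation is near one at every observed
#' lag is observationally a constant — neither is autocorrelation the
#' data can see. When the fitted range is resolvable inside the lag
#' span the fraction reduces to the classical
#' \code{psill / (nugget + psill)}. A fraction below the threshold
#' (default 0.2) is read as "no remaining spatial autocorrelation in
#' the residuals", i.e. the predictor exhausted the spatial structure.
#'
#' @param ps \linkS4class{PointSet} of CV residuals.
#' @param nBins,maxDist variogram binning.
#' @param minN minimum number of residuals (default 30).
#' @param threshold verdict threshold on the structure fraction.
#' @param family variogram family to fit.
#' @return list(residual_vgm, structure_fraction, verdict).
#' @export
residualAutocorrelation <- function(ps, nBins = 12L, maxDist = NULL,
                                    minN = 30L, threshold = 0.2,
                                    family = "exponential") {
  if (npoints(ps) < minN)
    stop("need at least ", minN, " residuals (got ", npoints(ps), ")")
  emp <- empiricalVariogram(ps, nBins = nBins, maxDist = maxDist)
  vg <- fitVariogram(emp, family)
  D <- cross_dist(ps@coords, ps@coords)
  diag(D) <- Inf
  hnn <- stats::median(apply(D, 1, min))
  hmax <- max(emp@lag)
  gHi <- semivariance(vg, hmax)
  sf <- if (gHi <= 0) 0 else (gHi - semivariance(vg, hnn)) / gHi
  list(residual_vgm = vg, structure_fraction = sf,
       verdict = if (sf < threshold) "no residual spatial autocorrelation"
                 else "residual spatial autocorrelation present")
}

#' Propose second-stage sampling locations from an error map
#'
#' Greedy allocation of new samples where the predicted error is
#' highest: cells are visited in decreasing sigma order (ties broken
#' row-major) and accepted when at least \code{minSpacing} away from
#' every already accepted location. If the spacing makes \code{nNew}
#' infeasible the maximal feasible set is returned with a warning.
#'
#' @param sigmaStack \linkS4class{CovariateStack} whose first layer is
#'   the prediction-error SD surface (or a plain matrix plus
#'   \code{grid}).
#' @param nNew number of new locations wanted.
#' @param minSpacing minimum pairwise distance (coordinate units).
#' @param grid needed when \code{sigmaStack} is a plain matrix.
#' @return Matrix of selected cell-center coordinates with attribute
#'   \code{sigma}.
#' @export
proposeSecondStage <- function(sigmaStack, nNew, minSpacing, grid = NULL) {
  if (methods::is(sigmaStack, "CovariateStack")) {
    grid <- sigmaStack@grid
    sig <- mat_to_vec(sigmaStack@layers[[1]])
    valid <- mat_to_vec(sigmaStack@mask)
  } else {
    if (is.null(grid)) stop("supply a GridSpec with a plain sigma matrix")
    sig <- mat_to_vec(sigmaStack)
    valid <- rep(TRUE, length(sig))
  }
  centers <- cellCenters(grid)
  ord <- order(-sig, seq_along(sig))           # ties row-major
  ord <- ord[valid[ord]]
  sel <- integer(0)
  for (cell in ord) {
    if (length(sel) >= nNew) break
    if (!length(sel) ||
        min(cross_dist(centers[cell, , drop = FALSE],
                       centers[sel, , drop = FALSE])) >= minSpacing)
      sel <- c(sel, cell)
  }
  if (length(sel) < nNew)
    warning("spacing constraint allows only ", length(sel), " of ", nNew,
            " requested locations", call. = FALSE)
  out <- centers[sel, , drop = FALSE]
  attr(out, "sigma") <- sig[sel]
  attr(out, "cells") <- sel
  out
}

## ---------------------------------------------------------------------
## Cross-validation with refitting
## ---------------------------------------------------------------------

default_levels <- c(seq(0.1, 0.9, 0.1), 0.6827, 0.95)

qs_for_levels <- function(levels)
  sort(unique(round(c((1 - levels) / 2, (1 + levels) / 2, 0.5, 0.159, 0.841),
                    9)))

## Built-in fit/predict recipes. Each returns list(yHat, sigma, quantiles).
recipe_ok <- function(train, test, stacks, grid, control, qs, foldSeed) {
  vg <- control$vgm
  if (is.null(vg)) {
    emp <- empiricalVariogram(train, nBins = control$nBins %||% 15L,
                              maxDist = control$maxDist)
    vg <- fitVariogram(emp, control$family %||% "exponential")
  }
  kr <- okPredict(train, coords(test), vg)
  sigma <- sqrt(kr@variances)
  list(yHat = kr@predictions, sigma = sigma,
       quantiles = outer_quantiles_gaussian(kr@predictions, sigma, qs),
       info = list(vgm = vg))
}

recipe_rk <- function(train, test, stacks, grid, control, qs, foldSeed) {
  kr <- rkPredict(train, stacks[[1]], targets = coords(test),
                  family = control$family %||% "exponential",
                  eta = control$eta, nBins = control$nBins %||% 15L,
                  maxDist = control$maxDist)
  sigma <- sqrt(kr@variances)
  list(yHat = kr@predictions, sigma = sigma,
       quantiles = outer_quantiles_gaussian(kr@predictions, sigma, qs),
       info = list(residVgm = kr@details$residVgm))
}

recipe_rfsp <- function(train, test, stacks, grid, control, qs, foldSeed) {
  bufs <- bufferDistances(train, grid, cap = control$bufferCap %||% 1000L)
  allStacks <- c(list(bufs), stacks)
  design <- buildDesign(train, allStacks)
  params <- control$forest %||% forestParams()
  params@seed <- foldSeed
  if (isTRUE(control$useCaseWeights) &&
      !is.null(attr(design, "caseWeights")))
    params@caseWeights <- attr(design, "caseWeights")
  model <- fitForest(design, params)
  X0 <- do.call(cbind, lapply(allStacks, function(s)
    suppressWarnings(overlayPoints(test, s))))
  if (!is.null(test@time)) X0 <- cbind(X0, temporalCovariates(test@time))
  qp <- predictQuantiles(model, X0, qs)
  list(yHat = qp@mean, sigma = qp@sigma, quantiles = qp@values,
       info = list(nBufferLayers = nLayers(bufs), oobMse = model@oobMse))
}

outer_quantiles_gaussian <- function(mu, sigma, qs) {
  q <- outer(sigma, stats::qnorm(qs)) + mu
  colnames(q) <- paste0("q", qs)
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' k-fold cross-validation with refitting
#'
#' Runs the comparison protocol used to benchmark spatial predictors:
#' random k-fold CV in which everything is refitted on each training
#' subset — the variogram for kriging, and for the forest the
#' buffer-distance layers themselves, which are rebuilt from the
#' training-fold points only (no leakage of held-out locations into the
#' geographic covariates; this makes forest CV k times more expensive
#' but honest). Held-out points receive a prediction, a prediction-error
#' SD and a set of conditional quantiles, from which the metric battery,
#' z-score calibration, interval coverage and the CV-residual variogram
#' are assembled.
#'
#' @param ps a \linkS4class{PointSet} with numeric target.
#' @param method "ok", "rk", "rfsp", or a custom recipe: a list with
#'   elements \code{name} and \code{fun(train, test, stacks, grid,
#'   control, qs, foldSeed)} returning list(yHat, sigma, quantiles).
#' @param stacks optional list of thematic covariate stacks.
#' @param grid prediction grid used to rasterize per-fold buffer
#'   distances (defaults to the first stack's grid).
#' @param k number of folds.
#' @param seed seed for the fold split and all per-fold refits.
#' @param control method options: \code{vgm} (fixed variogram for "ok"),
#'   \code{family}, \code{nBins}, \code{maxDist}, \code{eta},
#'   \code{forest} (a \linkS4class{ForestParams}), \code{useCaseWeights},
#'   \code{levels} (nominal coverage levels), \code{residMinN}.
#' @return A \linkS4class{CVReport}.
#' @export
crossValidate <- function(ps, method = c("ok", "rk", "rfsp"),
                          stacks = NULL, grid = NULL, k = 5L, seed = 1L,
                          control = list()) {
  if (methods::is(stacks, "CovariateStack")) stacks <- list(stacks)
  if (is.null(grid) && length(stacks)) grid <- stacks[[1]]@grid
  if (is.character(method)) {
    method <- match.arg(method)
    fun <- switch(method, ok = recipe_ok, rk = recipe_rk, rfsp = recipe_rfsp)
    name <- method
  } else {
    fun <- method$fun
    name <- method$name %||% "custom"
  }
  n <- npoints(ps)
  levels <- control$levels %||% default_levels
  qs <- qs_for_levels(levels)
  fold <- kfoldSplit(n, k, seed = seed)
  foldSeeds <- derive_seeds(seed, k)
  yHat <- sigmaHat <- rep(NA_real_, n)
  Q <- matrix(NA_real_, n, length(qs), dimnames = list(NULL, paste0("q", qs)))
  foldInfo <- vector("list", k)
  for (f in seq_len(k)) {
    teIdx <- which(fold == f)
    trIdx <- which(fold != f)
    train <- ps[trIdx]; test <- ps[teIdx]
    if (length(unique(as.numeric(train@target))) < 2L)
      stop("degenerate training data in fold ", f)
    res <- tryCatch(fun(train, test, stacks, grid, control, qs, foldSeeds[f]),
                    error = function(e)
                      stop("cross-validation aborted in fold ", f, ": ",
                           conditionMessage(e), call. = FALSE))
    yHat[teIdx] <- res$yHat
    sigmaHat[teIdx] <- res$sigma
    Q[teIdx, ] <- res$quantiles
    foldInfo[[f]] <- c(list(nTrain = length(trIdx)), res$info)
  }
  yObs <- as.numeric(ps@target)
  metrics <- computeMetrics(yObs, yHat)
  zs <- if (all(sigmaHat == 0)) list(z_mean = NA_real_, z_var = NA_real_,
                                     n_excluded = n)
        else zscoreStats(yObs, yHat, sigmaHat)
  metrics$z_mean <- zs$z_mean
  metrics$z_var <- zs$z_var
  metrics$z_excluded <- zs$n_excluded
  coverage <- coverageTable(yObs, Q, qs = qs, levels = levels)
  residVgm <- NULL; sf <- NA_real_
  if (n >= (control$residMinN %||% 30L)) {
    ra <- residualAutocorrelation(
      PointSet(ps@coords, yObs - yHat, ids = ps@ids),
      minN = control$residMinN %||% 30L)
    residVgm <- ra$residual_vgm
    sf <- ra$structure_fraction
  }
  new("CVReport", method = name, foldOf = fold, yObs = yObs, yHat = yHat,
      sigmaHat = sigmaHat, quantiles = Q, qs = qs, metrics = metrics,
      coverage = coverage, residualVgm = residVgm,
      structureFraction = sf, details = list(folds = foldInfo, seed = seed))
}

#' Serialize a CVReport
#'
#' Writes the metric battery, coverage table and residual-variogram
#' parameters as JSON plus the per-point columns as CSV.
#'
#' @param report a \linkS4class{CVReport}.
#' @param jsonPath,csvPath output files (skipped when NULL).
#' @return The JSON-able list, invisibly.
#' @export
writeCVReport <- function(report, jsonPath = NULL, csvPath = NULL) {
  out <- list(
    method = report@method,
    n = length(report@yObs),
    k = length(unique(report@foldOf)),
    metrics = report@metrics[c("rmse", "me", "r2", "ccc", "rho",
                               "z_mean", "z_var", "z_excluded")],
    coverage = report@coverage,
    residual_variogram = if (is.null(report@residualVgm)) NULL else list(
      family = vgmFamily(report@residualVgm),
      nugget = nugget(report@residualVgm),
      psill = psill(report@residualVgm),
      range = rangeParam(report@residualVgm),
      structure_fraction = report@structureFraction))
  if (!is.null(jsonPath))
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", dataframe = "columns")
  if (!is.null(csvPath))
    utils::write.csv(data.frame(fold = report@foldOf, y_obs = report@yObs,
                                y_hat = report@yHat,
                                sigma_hat = report@sigmaHat),
                     csvPath, row.names = FALSE)
  invisible(out)
}

#' Diagnostic panels for a CVReport
#'
#' Draws the four standard panels: predicted vs observed, z-score
#' histogram, the accuracy plot (empirical vs nominal interval
#' coverage), and the CV-residual variogram structure.
#'
#' @param report a \linkS4class{CVReport}.
#' @param file optional PNG path; when given the panels are written
#'   there instead of the active device.
#' @return \code{file} (or NULL), invisibly.
#' @export
plotCVReport <- function(report, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 1000, res = 130)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  lim <- range(c(report@yObs, report@yHat))
  plot(report@yObs, report@yHat, xlab = "observed", ylab = "predicted",
       main = paste0("predicted vs observed (", report@method, ")"),
       xlim = lim, ylim = lim, pch = 16, cex = 0.6)
  graphics::abline(0, 1, col = "grey40")
  z <- (report@yHat - report@yObs) / ifelse(report@sigmaHat > 0,
                                            report@sigmaHat, NA)
  graphics::hist(z, breaks = 30, main = "z-scores", xlab = "z")
  if (!is.null(report@coverage)) {
    plot(report@coverage$nominal, report@coverage$empirical,
         xlim = c(0, 1), ylim = c(0, 1), pch = 16,
         xlab = "nominal level", ylab = "empirical coverage",
         main = "accuracy plot")
    graphics::abline(0, 1, col = "grey40")
  }
  resid <- report@yObs - report@yHat
  if (!is.null(report@residualVgm)) {
    h <- seq(0, max(practicalRange(report@residualVgm) * 1.3, 1),
             length.out = 100)
    plot(h, semivariance(report@residualVgm, h), type = "l",
         xlab = "distance", ylab = "semivariance",
         main = sprintf("CV-residual variogram (structure %.2f)",
                        report@structureFraction))
  } else {
    graphics::hist(resid, breaks = 30, main = "CV residuals",
                   xlab = "residual")
  }
  invisible(file)
}
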