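## Ordinary kriging, the MLR trend model, log-normal back-transform and
## regression kriging.

#' Ordinary kriging prediction with variance
#'
#' For each target location s0 solves the augmented system
#' \deqn{[[C, 1], [1', 0]] [w, phi]' = [C0, 1]'}
#' where C is the covariance matrix among the observations and C0 the
#' covariance vector to s0, giving the best linear unbiased predictor
#' \code{yhat = w'y} under the unit-sum constraint, and the kriging
#' variance \code{C(s0,s0) - w'C0 - phi}. The default neighborhood is
#' global; \code{nmax} switches to a nearest-m local neighborhood for
#' large n.
#'
#' @param ps a \linkS4class{PointSet} with a numeric target. Duplicate
#'   coordinates are only permitted when the model has a positive
#'   nugget; with a zero nugget they make the system singular and raise
#'   an error naming the offending pairs.
#' @param targets two-column matrix of prediction locations.
#' @param vgm a \linkS4class{VariogramModel}.
#' @param nmax optional neighborhood size (nearest observations used
#'   per target).
#' @param keepWeights store the weight matrix and Lagrange multipliers
#'   (global neighborhood only).
#' @return A \linkS4class{KrigingResult}.
#' @export
okPredict <- function(ps, targets, vgm, nmax = NULL, keepWeights = FALSE) {
  if (!is.numeric(ps@target)) stop("ordinary kriging needs a numeric target")
  y <- as.numeric(ps@target)
  X <- ps@coords
  n <- nrow(X)
  targets <- matrix(as.numeric(targets), ncol = 2)
  dup <- duplicated(X) | duplicated(X, fromLast = TRUE)
  if (vgm@nugget == 0 && any(dup))
    stop("duplicate coordinates with a zero-nugget model make the kriging ",
         "system singular (points: ",
         paste(ps@ids[dup], collapse = ", "), ")")
  sill0 <- vgm@nugget + vgm@psill          # C(s0, s0)
  solve_block <- function(obsIdx, tg) {
    m <- length(obsIdx)
    D <- cross_dist(X[obsIdx, , drop = FALSE], X[obsIdx, , drop = FALSE])
    C <- vgm@psill * vgm_rho(vgm@family, D, vgm@rangeParam)
    diag(C) <- sill0
    A <- rbind(cbind(C, 1), c(rep(1, m), 0))
    D0 <- cross_dist(X[obsIdx, , drop = FALSE], tg)
    C0 <- vgm@psill * vgm_rho(vgm@family, D0, vgm@rangeParam) +
      vgm@nugget * (D0 == 0)
    rhs <- rbind(C0, 1)
    sol <- tryCatch(solve(A, rhs), error = function(e)
      stop("singular kriging system: ", conditionMessage(e), call. = FALSE))
    w <- sol[seq_len(m), , drop = FALSE]
    phi <- sol[m + 1L, ]
    pred <- drop(crossprod(w, y[obsIdx]))
    var <- sill0 - colSums(w * C0) - phi
    list(w = w, phi = phi, pred = pred, var = var)
  }
  if (is.null(nmax) || nmax >= n) {
    s <- solve_block(seq_len(n), targets)
    pred <- s$pred; var <- s$var
    W <- if (keepWeights) s$w else NULL
    phi <- if (keepWeights) s$phi else NULL
  } else {
    D0all <- cross_dist(X, targets)
    pred <- var <- numeric(nrow(targets))
    W <- NULL; phi <- NULL
    for (j in seq_len(nrow(targets))) {
      nb <- order(D0all[, j])[seq_len(nmax)]
      s <- solve_block(nb, targets[j, , drop = FALSE])
      pred[j] <- s$pred; var[j] <- s$var
    }
  }
  if (min(var) < -1e-6)
    warning("negative kriging variance beyond solver tolerance: ",
            min(var), call. = FALSE)
  var <- pmax(var, 0)
  new("KrigingResult", predictions = as.numeric(pred),
      variances = as.numeric(var), weights = W, lagrange = phi,
      details = list(vgm = vgm))
}

#' Log-normal back-transform of kriging results
#'
#' Converts a prediction and variance obtained on the log scale back to
#' the natural scale using the exact lognormal moments:
#' \code{yhat = exp(yT + varT/2)} and
#' \code{var = exp(2 yT + varT) (exp(varT) - 1)}.
#'
#' @param yT predictions on the log scale.
#' @param varT kriging variances on the log scale (>= 0).
#' @param muKnown flag recording whether the log-scale mean was treated
#'   as known (simple kriging); informational.
#' @return list with \code{prediction} and \code{variance}.
#' @export
lognormalBacktransform <- function(yT, varT, muKnown = TRUE) {
  if (any(varT < 0)) stop("varT must be non-negative")
  big <- 2 * yT + varT > 700
  if (any(big)) warning("overflow guard: ", sum(big),
                        " value(s) too large to back-transform", call. = FALSE)
  list(prediction = exp(yT + 0.5 * varT),
       variance = exp(2 * yT + varT) * (exp(varT) - 1),
       muKnown = muKnown)
}

#' Fit a multiple linear regression trend
#'
#' Ordinary least squares with rank-deficiency handling: collinear
#' columns are dropped with a warning. Needs n > p; with more
#' covariates than observations use \code{\link{fitForest}}, which
#' tolerates p >= n.
#'
#' @param X covariate data.frame (may have zero columns for an
#'   intercept-only trend).
#' @param y numeric response.
#' @return A \linkS4class{TrendModel}.
#' @export
fitTrend <- function(X, y) {
  X <- as.data.frame(X)
  n <- length(y)
  if (n <= ncol(X) + 1L)
    stop("n <= p: the linear trend is not estimable; ",
         "use fitForest, which tolerates p >= n")
  df <- cbind(X, .y = y)
  fit <- stats::lm(.y ~ ., data = df)
  beta <- stats::coef(fit)
  dropped <- names(beta)[is.na(beta)]
  if (length(dropped)) {
    warning("rank-deficient design; dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    keep <- setdiff(colnames(X), dropped)
    df <- cbind(X[, keep, drop = FALSE], .y = y)
    fit <- stats::lm(.y ~ ., data = df)
    beta <- stats::coef(fit)
  } else dropped <- NULL
  p <- length(beta)
  mse <- sum(stats::residuals(fit)^2) / (n - p)
  new("TrendModel", fit = fit, beta = beta, mse = mse, p = as.integer(p),
      dropped = dropped)
}

#' Predict from a linear trend with prediction-error variance
#'
#' The variance at x0 is \code{MSE * (1 + x0' (X'X)^-1 x0)}: smallest
#' where the covariates sit at the center of the feature space and
#' growing with leverage (extrapolation in feature space).
#'
#' @param tm a \linkS4class{TrendModel}.
#' @param X0 covariate rows at the prediction locations.
#' @return list with \code{prediction} and \code{variance}.
#' @export
predictTrend <- function(tm, X0) {
  X0 <- as.data.frame(X0)
  pr <- stats::predict(tm@fit, newdata = X0, se.fit = TRUE)
  list(prediction = as.numeric(pr$fit),
       variance = as.numeric(pr$se.fit^2 + tm@mse))
}

#' Regression kriging
#'
#' Runs the standard trend-plus-residual pipeline: (1) overlay points on
#' the covariate stack, (2) fit the MLR trend (optionally after a
#' Box-Cox transform of the target), (3) estimate and fit the residual
#' variogram, (4) predict the trend at the target locations, (5) krige
#' the residuals there, (6) sum the two, and (7) back-transform if a
#' transform was used. The reported variance is the sum of the trend and
#' residual-kriging variances; the cross-term of an integrated
#' universal-kriging solver is omitted, so the variance is approximate.
#'
#' @param ps a \linkS4class{PointSet} with numeric target.
#' @param stack covariates available at points and targets.
#' @param targets two-column matrix of prediction locations; default all
#'   valid cell centers of the stack.
#' @param family residual variogram family.
#' @param eta optional Box-Cox exponent; \code{eta = 0} (log) uses the
#'   exact lognormal back-transform of prediction and variance, other
#'   values back-transform the prediction only (variance stays on the
#'   transformed scale, with a warning).
#' @param nBins,maxDist passed to \code{\link{empiricalVariogram}}.
#' @param residVgm optional pre-fitted residual
#'   \linkS4class{VariogramModel}; skips steps 3's fit.
#' @return A \linkS4class{KrigingResult}; \code{details} carries the
#'   trend model and residual variogram.
#' @export
rkPredict <- function(ps, stack, targets = NULL,
                      family = "exponential", eta = NULL,
                      nBins = 15L, maxDist = NULL, residVgm = NULL) {
  if (is.null(targets)) {
    centers <- cellCenters(stack)
    targets <- centers[mat_to_vec(stack@mask), , drop = FALSE]
  }
  X <- overlayPoints(ps, stack)
  ok <- stats::complete.cases(X)
  ps <- ps[which(ok)]
  X <- X[ok, , drop = FALSE]
  y <- as.numeric(ps@target)
  yT <- if (is.null(eta)) y else boxcox(y, eta)
  tm <- fitTrend(X, yT)
  resid <- as.numeric(stats::residuals(tm@fit))
  if (is.null(residVgm)) {
    emp <- empiricalVariogram(PointSet(ps@coords, resid),
                              nBins = nBins, maxDist = maxDist)
    residVgm <- fitVariogram(emp, family)
  }
  idxT <- cellIndex(stack@grid, targets)
  X0 <- as.data.frame(lapply(stack@layers, function(l)
    l[cbind(idxT$row, idxT$col)]))
  tr <- predictTrend(tm, X0)
  kr <- okPredict(PointSet(ps@coords, resid, ids = ps@ids), targets, residVgm)
  predT <- tr$prediction + kr@predictions
  varT <- tr$variance + kr@variances
  if (is.null(eta)) {
    pred <- predT; var <- varT
  } else if (eta == 0) {
    bt <- lognormalBacktransform(predT, varT)
    pred <- bt$prediction; var <- bt$variance
  } else {
    warning("Box-Cox back-transform with eta != 0 is applied to the ",
            "prediction only; variance stays on the transformed scale",
            call. = FALSE)
    pred <- boxcoxInverse(predT, eta); var <- varT
  }
  new("KrigingResult", predictions = pred, variances = var,
      weights = NULL, lagrange = NULL,
      details = list(trend = tm, residVgm = residVgm, eta = eta,
                     predT = predT, varT = varT))
}
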