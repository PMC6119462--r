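## Core S4 classes: spatial point sets, grid/raster stacks, variogram
## models, forest models and cross-validation reports.

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))
setClassUnion("DateOrNULL", c("Date", "NULL"))
setClassUnion("targetVector", c("numeric", "factor"))

## ---------------------------------------------------------------------
## PointSet
## ---------------------------------------------------------------------

#' Point observations of a spatial (or spatiotemporal) variable
#'
#' A \code{PointSet} holds sampling locations in projected planar
#' coordinates together with the observed target (numeric or
#' categorical), optional observation dates, optional per-point
#' measurement-error standard deviations, and optional type/method
#' labels used by multivariate (stacked) models.
#'
#' @slot ids character point labels.
#' @slot coords two-column numeric matrix of planar coordinates, in the
#'   same units as any grid the points are combined with.
#' @slot time optional \code{Date} vector (one per point).
#' @slot target numeric values or a factor of class labels.
#' @slot measSd optional per-point measurement-error SD (target units,
#'   strictly positive).
#' @slot typeLabel optional per-point variable-type tag (e.g., which
#'   chemical element a row measures in a multivariate survey).
#' @slot methodLabel optional per-point sampling-method tag.
#'
#' @export
setClass("PointSet",
  representation(
    ids = "character",
    coords = "matrix",
    time = "DateOrNULL",
    target = "targetVector",
    measSd = "numericOrNULL",
    typeLabel = "characterOrNULL",
    methodLabel = "characterOrNULL"
  )
)

setValidity("PointSet", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (n < 1L) msg <- c(msg, "a PointSet needs at least one point")
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have two columns")
  if (!is.numeric(object@coords) || any(!is.finite(object@coords)))
    msg <- c(msg, "all coordinates must be finite numbers")
  if (length(object@target) != n)
    msg <- c(msg, "target length must equal the number of points")
  if (length(object@ids) != n)
    msg <- c(msg, "ids length must equal the number of points")
  if (!is.null(object@time) && length(object@time) != n)
    msg <- c(msg, "time length must equal the number of points")
  if (!is.null(object@measSd)) {
    if (length(object@measSd) != n)
      msg <- c(msg, "measSd length must equal the number of points")
    else if (any(!is.finite(object@measSd)) || any(object@measSd <= 0))
      msg <- c(msg, "measSd must be strictly positive for every point")
  }
  if (!is.null(object@typeLabel) && length(object@typeLabel) != n)
    msg <- c(msg, "typeLabel length must equal the number of points")
  if (!is.null(object@methodLabel) && length(object@methodLabel) != n)
    msg <- c(msg, "methodLabel length must equal the number of points")
  if (length(msg)) msg else TRUE
})

#' Construct a PointSet
#'
#' @param coords two-column matrix (or data.frame) of x/y coordinates.
#' @param target numeric vector, or character/factor for categorical
#'   targets. A PointSet is always all-numeric or all-categorical.
#' @param ids optional labels (default \code{"p1".."pn"}).
#' @param time optional \code{Date} vector or anything
#'   \code{as.Date()} accepts.
#' @param measSd optional per-point measurement-error SD.
#' @param typeLabel,methodLabel optional per-point tags (scalars are
#'   recycled) used by multivariate stacked designs.
#'
#' @details Duplicate coordinates are allowed (real surveys contain
#' them) but flagged with a warning, because they make a zero-nugget
#' kriging system singular.
#'
#' @return A \linkS4class{PointSet}.
#' @export
PointSet <- function(coords, target, ids = NULL, time = NULL,
                     measSd = NULL, typeLabel = NULL, methodLabel = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  n <- nrow(coords)
  if (is.character(target)) target <- factor(target)
  if (is.null(ids)) ids <- paste0("p", seq_len(n))
  if (!is.null(time)) time <- as.Date(time)
  recycle <- function(v) if (!is.null(v) && length(v) == 1L) rep(v, n) else v
  typeLabel <- recycle(typeLabel)
  methodLabel <- recycle(methodLabel)
  measSd <- if (is.null(measSd)) NULL else as.numeric(recycle(measSd))
  ps <- new("PointSet", ids = as.character(ids), coords = coords,
            time = time, target = target, measSd = measSd,
            typeLabel = typeLabel, methodLabel = methodLabel)
  if (anyDuplicated(coords))
    warning("PointSet contains duplicated coordinates; ",
            "zero-nugget kriging systems will be singular", call. = FALSE)
  ps
}

## ---------------------------------------------------------------------
## GridSpec / CovariateStack
## ---------------------------------------------------------------------

#' Regular north-up prediction grid
#'
#' Cell centers are at \code{origin + (j - 0.5) * cellSize} horizontally
#' and \code{origin - (i - 0.5) * cellSize} vertically (row-major,
#' row 1 at the top). Cell membership uses half-open intervals so every
#' in-extent point maps to exactly one cell.
#'
#' @slot origin numeric length 2: x of the left edge, y of the top edge.
#' @slot cellSize positive cell edge length (coordinate units).
#' @slot nrows,ncols positive integers.
#' @slot crsTag opaque identifier of the projected reference system.
#' @export
setClass("GridSpec",
  representation(origin = "numeric", cellSize = "numeric",
                 nrows = "integer", ncols = "integer", crsTag = "character")
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite numbers (x left, y top)")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (object@nrows < 1L || object@ncols < 1L)
    msg <- c(msg, "nrows and ncols must be at least 1")
  if (length(msg)) msg else TRUE
})

#' @rdname GridSpec-class
#' @param nrows,ncols grid dimensions.
#' @param cellSize cell edge length.
#' @param origin x of the left edge and y of the top edge; the default
#'   puts the lower-left corner of the grid at (0, 0).
#' @param crsTag opaque CRS identifier (informational only; the package
#'   never reprojects).
#' @return A \linkS4class{GridSpec}.
#' @export
GridSpec <- function(nrows, ncols, cellSize = 1,
                     origin = c(0, nrows * cellSize), crsTag = "local") {
  new("GridSpec", origin = as.numeric(origin), cellSize = as.numeric(cellSize),
      nrows = as.integer(nrows), ncols = as.integer(ncols),
      crsTag = as.character(crsTag))
}

#' A named stack of raster covariate layers on a common grid
#'
#' @slot grid the \linkS4class{GridSpec}.
#' @slot layers named list of \code{nrows x ncols} numeric matrices.
#' @slot roles character vector (same names as layers), each one of
#'   \code{"geographic"}, \code{"reflectance"} or \code{"process"}.
#' @slot mask logical matrix; \code{FALSE} cells are excluded from
#'   prediction and overlay.
#' @export
setClass("CovariateStack",
  representation(grid = "GridSpec", layers = "list",
                 roles = "character", mask = "matrix")
)

setValidity("CovariateStack", function(object) {
  msg <- character()
  nr <- object@grid@nrows; nc <- object@grid@ncols
  nms <- names(object@layers)
  if (length(object@layers) && (is.null(nms) || anyDuplicated(nms) ||
      any(nms == "")))
    msg <- c(msg, "layers must have unique non-empty names")
  for (l in object@layers)
    if (!is.matrix(l) || nrow(l) != nr || ncol(l) != nc) {
      msg <- c(msg, "every layer must be an nrows x ncols matrix")
      break
    }
  if (!identical(dim(object@mask), c(nr, nc)))
    msg <- c(msg, "mask must be an nrows x ncols logical matrix")
  if (length(object@roles) != length(object@layers) ||
      !all(object@roles %in% c("geographic", "reflectance", "process")))
    msg <- c(msg, "roles must tag every layer as geographic|reflectance|process")
  if (length(msg)) msg else TRUE
})

#' @rdname CovariateStack-class
#' @param grid a \linkS4class{GridSpec}.
#' @param layers named list of matrices.
#' @param roles layer roles; a scalar is recycled. Default "process".
#' @param mask logical validity matrix (default all valid).
#' @return A \linkS4class{CovariateStack}.
#' @export
CovariateStack <- function(grid, layers, roles = "process", mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, grid@nrows, grid@ncols)
  if (length(roles) == 1L) roles <- rep(roles, length(layers))
  names(roles) <- names(layers)
  layers <- lapply(layers, function(l) {
    storage.mode(l) <- "double"; l
  })
  new("CovariateStack", grid = grid, layers = layers,
      roles = roles, mask = mask)
}

#' Buffer-distance covariate stack
#'
#' A \linkS4class{CovariateStack} whose layers are Euclidean distance
#' surfaces, one per source observation point (or per class), plus the
#' bookkeeping of which source each layer refers to.
#'
#' @slot sourceIds point ids or class labels, one per layer.
#' @export
setClass("BufferDistanceStack", contains = "CovariateStack",
         representation(sourceIds = "character"))

setValidity("BufferDistanceStack", function(object) {
  if (length(object@sourceIds) != length(object@layers))
    "sourceIds must have one entry per layer" else TRUE
})

## ---------------------------------------------------------------------
## Variograms
## ---------------------------------------------------------------------

#' Sample (empirical) variogram
#'
#' Method-of-moments semivariance estimates per distance bin; bins with
#' zero pairs are dropped.
#'
#' @slot lag mean pair distance per populated bin (strictly increasing).
#' @slot gamma semivariance estimate per bin.
#' @slot npairs pair count per bin.
#' @slot maxDist,nBins the binning used.
#' @export
setClass("EmpiricalVariogram",
  representation(lag = "numeric", gamma = "numeric", npairs = "numeric",
                 maxDist = "numeric", nBins = "integer")
)

setValidity("EmpiricalVariogram", function(object) {
  msg <- character()
  if (length(object@lag) != length(object@gamma) ||
      length(object@lag) != length(object@npairs))
    msg <- c(msg, "lag, gamma and npairs must be the same length")
  if (is.unsorted(object@lag, strictly = TRUE))
    msg <- c(msg, "lag centers must be strictly increasing")
  if (any(object@npairs <= 0))
    msg <- c(msg, "bins with zero pairs carry no estimate")
  if (length(msg)) msg else TRUE
})

#' Parametric variogram / covariance model
#'
#' Isotropic model with nugget tau^2, partial sill sigma_p^2 and range
#' parameter phi for a named correlation family. The covariance is
#' \code{C(h) = sigma_p^2 * rho(h / phi)} for h > 0 with
#' \code{C(0) = tau^2 + sigma_p^2}, and
#' \code{gamma(h) = tau^2 + sigma_p^2 * (1 - rho(h/phi))} so that
#' \code{gamma(h) + C(h)} equals the total sill for h > 0.
#'
#' @slot family one of "exponential", "spherical", "gaussian",
#'   "pure-nugget".
#' @slot nugget tau^2 (>= 0).
#' @slot psill partial sill sigma_p^2 (>= 0).
#' @slot rangeParam phi (> 0; ignored for pure nugget).
#' @slot eta optional Box-Cox exponent recorded when the model was fitted
#'   on transformed data.
#' @export
setClass("VariogramModel",
  representation(family = "character", nugget = "numeric", psill = "numeric",
                 rangeParam = "numeric", eta = "numericOrNULL")
)

setValidity("VariogramModel", function(object) {
  msg <- character()
  if (!object@family %in% c("exponential", "spherical", "gaussian",
                            "pure-nugget"))
    msg <- c(msg, "unknown correlation family")
  if (object@nugget < 0 || object@psill < 0)
    msg <- c(msg, "nugget and partial sill must be non-negative")
  if (object@family != "pure-nugget" && object@rangeParam <= 0)
    msg <- c(msg, "range parameter must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname VariogramModel-class
#' @param family correlation family.
#' @param nugget,psill,rangeParam model parameters.
#' @param eta optional Box-Cox exponent metadata.
#' @return A \linkS4class{VariogramModel}.
#' @export
variogramModel <- function(family = c("exponential", "spherical", "gaussian",
                                      "pure-nugget"),
                           nugget = 0, psill = 1, rangeParam = 1, eta = NULL) {
  family <- match.arg(family)
  new("VariogramModel", family = family, nugget = as.numeric(nugget),
      psill = as.numeric(psill),
      rangeParam = as.numeric(if (family == "pure-nugget") 1 else rangeParam),
      eta = eta)
}

#' Multiple linear regression trend model
#'
#' Ordinary least-squares trend with the bookkeeping needed for the
#' prediction-error variance \code{MSE * (1 + x0' (X'X)^-1 x0)}.
#'
#' @slot fit the underlying \code{lm} fit.
#' @slot beta estimated coefficients (dropped columns excluded).
#' @slot mse residual variance estimate, SSE / (n - p).
#' @slot p number of estimated coefficients.
#' @slot dropped names of covariates dropped for rank deficiency.
#' @export
setClass("TrendModel",
  representation(fit = "ANY", beta = "numeric", mse = "numeric",
                 p = "integer", dropped = "characterOrNULL"))

#' Kriging predictions with variances
#'
#' @slot predictions point predictions at the target locations.
#' @slot variances kriging variances (>= 0 up to solver tolerance).
#' @slot weights optional n x m matrix of kriging weights (columns sum
#'   to one).
#' @slot lagrange optional Lagrange multipliers, one per target.
#' @slot details list of component objects (trend model, variogram, ...)
#'   for composite predictors such as regression kriging.
#' @export
setClass("KrigingResult",
  representation(predictions = "numeric", variances = "numeric",
                 weights = "ANY", lagrange = "numericOrNULL",
                 details = "list"))

## ---------------------------------------------------------------------
## Forests
## ---------------------------------------------------------------------

#' Tuning parameters of a spatial random forest
#'
#' @slot numTrees number of trees B.
#' @slot mtry candidate covariates per split; \code{NA} picks the
#'   default (\code{floor(p/3)} for regression, \code{floor(sqrt(p))}
#'   for probability forests, at least 1). For spatiotemporal problems
#'   where one or two covariates dominate it is advisable to keep mtry
#'   high (above p/2).
#' @slot minNodeSize minimal terminal node size; \code{NA} picks 5
#'   (regression) or 10 (probability).
#' @slot sampleFraction bootstrap fraction in (0, 1].
#' @slot replace bootstrap with replacement?
#' @slot caseWeights optional per-observation sampling weights
#'   (>= 0, at least one positive); observations with weight zero never
#'   enter a bootstrap sample.
#' @slot seed RNG seed (\code{NA} for unseeded).
#' @slot task "regression" or "probability".
#' @export
setClass("ForestParams",
  representation(numTrees = "integer", mtry = "integer",
                 minNodeSize = "integer", sampleFraction = "numeric",
                 replace = "logical", caseWeights = "numericOrNULL",
                 seed = "integer", task = "character"))

setValidity("ForestParams", function(object) {
  msg <- character()
  if (object@numTrees < 1L) msg <- c(msg, "numTrees must be >= 1")
  if (!is.na(object@mtry) && object@mtry < 1L)
    msg <- c(msg, "mtry must be >= 1")
  if (object@sampleFraction <= 0 || object@sampleFraction > 1)
    msg <- c(msg, "sampleFraction must be in (0, 1]")
  if (!is.null(object@caseWeights)) {
    if (any(object@caseWeights < 0) || all(object@caseWeights == 0))
      msg <- c(msg, "caseWeights must be >= 0 with at least one > 0")
  }
  if (!object@task %in% c("regression", "probability"))
    msg <- c(msg, "task must be 'regression' or 'probability'")
  if (length(msg)) msg else TRUE
})

#' @rdname ForestParams-class
#' @param numTrees,mtry,minNodeSize,sampleFraction,replace,caseWeights,seed,task
#'   see the slot documentation.
#' @return A \linkS4class{ForestParams}.
#' @export
forestParams <- function(numTrees = 500L, mtry = NA, minNodeSize = NA,
                         sampleFraction = 1, replace = TRUE,
                         caseWeights = NULL, seed = NA,
                         task = c("regression", "probability")) {
  new("ForestParams", numTrees = as.integer(numTrees),
      mtry = as.integer(mtry), minNodeSize = as.integer(minNodeSize),
      sampleFraction = as.numeric(sampleFraction), replace = replace,
      caseWeights = caseWeights, seed = as.integer(seed),
      task = match.arg(task))
}

#' Fitted spatial random forest
#'
#' Wraps the fitted tree ensemble together with the bootstrap and
#' terminal-node bookkeeping that quantile-regression-forest weights
#' require, plus out-of-bag statistics and impurity importances.
#'
#' @slot forest the fitted \code{ranger} ensemble.
#' @slot trainY training targets (needed to invert the conditional CDF).
#' @slot trainNodes n x B matrix of terminal node ids of the training
#'   rows in every tree.
#' @slot inbag n x B matrix of bootstrap multiplicities.
#' @slot covariateNames design column names (order matters at predict
#'   time).
#' @slot params the \linkS4class{ForestParams} used.
#' @slot oobMse,oobR2 out-of-bag error statistics (NA when no
#'   observation was ever out of bag).
#' @slot importance impurity importance per covariate.
#' @slot typeLevels,methodLevels indicator levels of a multivariate
#'   design, or NULL.
#' @export
setClass("RFspModel",
  representation(forest = "ANY", trainY = "targetVector",
                 trainNodes = "matrix", inbag = "matrix",
                 covariateNames = "character", params = "ForestParams",
                 oobMse = "numeric", oobR2 = "numeric",
                 importance = "numeric",
                 typeLevels = "characterOrNULL",
                 methodLevels = "characterOrNULL"))

#' Quantile predictions from a forest
#'
#' @slot qs requested probabilities (sorted).
#' @slot values m x length(qs) matrix of quantile estimates,
#'   non-decreasing along each row.
#' @slot mean conditional-mean prediction (the weighted combination of
#'   the training observations).
#' @slot sigma prediction-error SD estimated as half the width of the
#'   central 68.27\% interval.
#' @slot weights optional m x n matrix of QRF observation weights
#'   (rows sum to one).
#' @export
setClass("QuantilePrediction",
  representation(qs = "numeric", values = "matrix", mean = "numeric",
                 sigma = "numeric", weights = "ANY"))

setValidity("QuantilePrediction", function(object) {
  msg <- character()
  if (is.unsorted(object@qs)) msg <- c(msg, "qs must be sorted")
  if (any(object@sigma < 0)) msg <- c(msg, "sigma must be non-negative")
  if (ncol(object@values) != length(object@qs))
    msg <- c(msg, "values must have one column per requested quantile")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## Cross-validation report
## ---------------------------------------------------------------------

#' Cross-validation report
#'
#' Per-point held-out predictions with uncertainty, the full metric
#' battery (RMSE, ME, R2, Lin's concordance, correlation, z-score
#' calibration), an interval-coverage table and a residual-variogram
#' diagnostic.
#'
#' @slot method label of the evaluated predictor.
#' @slot foldOf fold id per point.
#' @slot yObs,yHat,sigmaHat held-out observations, predictions and
#'   predicted error SDs.
#' @slot quantiles m x q matrix of held-out quantile predictions (or
#'   NULL).
#' @slot qs the quantile probabilities of \code{quantiles}.
#' @slot metrics named list: rmse, me, r2, ccc, rho, z_mean, z_var,
#'   z_excluded.
#' @slot coverage data.frame with nominal and empirical interval
#'   coverage (or NULL).
#' @slot residualVgm fitted variogram of the CV residuals (or NULL).
#' @slot structureFraction psill / (nugget + psill) of the residual
#'   variogram; values below ~0.2 indicate no remaining spatial
#'   autocorrelation in the residuals.
#' @slot details list with per-fold bookkeeping (training sizes,
#'   covariate counts, refitted models).
#' @export
setClass("CVReport",
  representation(method = "character", foldOf = "integer",
                 yObs = "numeric", yHat = "numeric", sigmaHat = "numeric",
                 quantiles = "ANY", qs = "numeric", metrics = "list",
                 coverage = "ANY", residualVgm = "ANY",
                 structureFraction = "numeric", details = "list"))

## ---------------------------------------------------------------------
## Synthetic-field specifications
## ---------------------------------------------------------------------

#' Specification of a synthetic Gaussian random field
#'
#' @slot grid the simulation grid.
#' @slot vgm generating variogram (nugget becomes iid micro-noise).
#' @slot trend optional list(intercept=, beta=, stack=) adding a linear
#'   trend in supplied covariate layers.
#' @slot transform "none" or "exp" (lognormal fields emulating skewed
#'   concentration data).
#' @slot seed RNG seed.
#' @export
setClass("FieldSpec",
  representation(grid = "GridSpec", vgm = "VariogramModel",
                 trend = "ANY", transform = "character", seed = "integer"))

#' @rdname FieldSpec-class
#' @param grid,vgm,trend,transform,seed see slots.
#' @return A \linkS4class{FieldSpec}.
#' @export
fieldSpec <- function(grid, vgm, trend = NULL,
                      transform = c("none", "exp"), seed = 1L) {
  new("FieldSpec", grid = grid, vgm = vgm, trend = trend,
      transform = match.arg(transform), seed = as.integer(seed))
}

#' Specification of a zero-inflated seasonal space-time field
#'
#' Emulates daily precipitation-like data: a seasonal mean cycle in
#' day-of-year, an AR(1)-evolving spatial Gaussian field across days,
#' iid nugget noise, and left-censoring at \code{zeroThreshold} which
#' produces the point mass at zero.
#'
#' @slot spatialVgm spatial variogram of the daily field.
#' @slot meanLevel latent mean level.
#' @slot seasonalAmplitude amplitude of the seasonal cycle (target
#'   units).
#' @slot seasonalPhase day-of-year at which the seasonal mean peaks.
#' @slot temporalCorr lag-1 autocorrelation of the daily fields,
#'   |a| < 1.
#' @slot zeroThreshold censoring level; latent values at or below it
#'   become exact zeros. The zero fraction is monotone in this value.
#' @slot seed RNG seed.
#' @export
setClass("SpaceTimeSpec",
  representation(spatialVgm = "VariogramModel", meanLevel = "numeric",
                 seasonalAmplitude = "numeric", seasonalPhase = "numeric",
                 temporalCorr = "numeric", zeroThreshold = "numeric",
                 seed = "integer"))

setValidity("SpaceTimeSpec", function(object) {
  if (abs(object@temporalCorr) >= 1)
    "temporalCorr must satisfy |a| < 1" else TRUE
})

#' @rdname SpaceTimeSpec-class
#' @param spatialVgm,meanLevel,seasonalAmplitude,seasonalPhase,temporalCorr,zeroThreshold,seed
#'   see slots. Defaults emulate a mid-latitude daily precipitation
#'   analogue: unit-sill exponential spatial structure, a seasonal cycle
#'   peaking in mid-July, day-to-day persistence 0.7 and a censoring
#'   level producing roughly 60\% dry observations.
#' @return A \linkS4class{SpaceTimeSpec}.
#' @export
spaceTimeSpec <- function(spatialVgm = variogramModel("exponential",
                                                      nugget = 0.1,
                                                      psill = 1,
                                                      rangeParam = 10),
                          meanLevel = 0, seasonalAmplitude = 1,
                          seasonalPhase = 196, temporalCorr = 0.7,
                          zeroThreshold = 0.5, seed = 1L) {
  new("SpaceTimeSpec", spatialVgm = spatialVgm,
      meanLevel = as.numeric(meanLevel),
      seasonalAmplitude = as.numeric(seasonalAmplitude),
      seasonalPhase = as.numeric(seasonalPhase),
      temporalCorr = as.numeric(temporalCorr),
      zeroThreshold = as.numeric(zeroThreshold), seed = as.integer(seed))
}
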