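## Spatial random forests: design construction on geographic + thematic
## covariates, forest fitting (via ranger), quantile-regression-forest
## weights and sigma, probability mapping, case-weighted bootstrap and
## multivariate type-indicator models.

#' Build a regression table from points and covariate stacks
#'
#' Overlays the observations on one or more covariate stacks and
#' assembles the forest design: one row per observation (per variable in
#' multivariate mode, where the rows of all point sets are stacked into
#' a single regression matrix and the type/method labels expand to 0/1
#' indicator columns). Rows with missing covariates are dropped with a
#' count.
#'
#' @param ps a \linkS4class{PointSet}, or a list of them in multivariate
#'   mode (each with its \code{typeLabel} set).
#' @param stacks a \linkS4class{CovariateStack} or list of stacks.
#' @param temporal optional data.frame from
#'   \code{\link{temporalCovariates}} (one row per observation); by
#'   default computed from the PointSet dates when present.
#' @param multivariate stack several variables into one design
#'   (type-indicator model).
#' @return data.frame with covariate columns plus a \code{y} column;
#'   attributes: \code{caseWeights} (\code{1 / measSd^2} when
#'   measurement-error SDs are recorded), \code{nDropped},
#'   \code{typeLevels}, \code{methodLevels}, \code{coords}.
#' @export
buildDesign <- function(ps, stacks, temporal = NULL, multivariate = FALSE) {
  if (methods::is(stacks, "CovariateStack")) stacks <- list(stacks)
  psList <- if (methods::is(ps, "PointSet")) list(ps) else ps
  if (multivariate) {
    bad <- vapply(psList, function(p) is.null(p@typeLabel), logical(1))
    if (any(bad))
      stop("multivariate mode requires a typeLabel on every PointSet")
  }
  rows <- lapply(psList, function(p) {
    covs <- do.call(cbind, lapply(stacks, function(s)
      suppressWarnings(overlayPoints(p, s))))
    df <- covs
    if (!is.null(temporal)) df <- cbind(df, temporal)
    else if (!is.null(p@time)) df <- cbind(df, temporalCovariates(p@time))
    df$y <- p@target
    df$.type <- if (is.null(p@typeLabel)) NA_character_ else p@typeLabel
    df$.method <- if (is.null(p@methodLabel)) NA_character_ else p@methodLabel
    df$.w <- if (is.null(p@measSd)) NA_real_ else 1 / p@measSd^2
    cbind(df, .x = p@coords[, 1], .y2 = p@coords[, 2])
  })
  df <- do.call(rbind, rows)
  typeLevels <- methodLevels <- NULL
  if (multivariate) {
    typeLevels <- sort(unique(df$.type))
    for (lv in typeLevels) df[[paste0("TYPE_", lv)]] <- as.numeric(df$.type == lv)
    if (!all(is.na(df$.method))) {
      methodLevels <- sort(unique(df$.method))
      for (lv in methodLevels)
        df[[paste0("METHOD_", lv)]] <- as.numeric(df$.method == lv)
    }
  }
  weights <- if (all(is.na(df$.w))) NULL else df$.w
  coordsMat <- cbind(df$.x, df$.y2)
  df$.type <- df$.method <- df$.w <- df$.x <- df$.y2 <- NULL
  keep <- stats::complete.cases(df[, setdiff(names(df), "y"), drop = FALSE])
  nDropped <- sum(!keep)
  if (nDropped > 0)
    warning(nDropped, " row(s) with missing covariates dropped", call. = FALSE)
  if (!any(keep)) stop("no complete rows in the design")
  df <- df[keep, , drop = FALSE]
  attr(df, "caseWeights") <- if (is.null(weights)) NULL else weights[keep]
  attr(df, "nDropped") <- nDropped
  attr(df, "typeLevels") <- typeLevels
  attr(df, "methodLevels") <- methodLevels
  attr(df, "coords") <- coordsMat[keep, , drop = FALSE]
  df
}

resolve_params <- function(params, p, n) {
  mtry <- params@mtry
  if (is.na(mtry))
    mtry <- if (params@task == "regression") max(1L, floor(p / 3))
            else max(1L, floor(sqrt(p)))
  mtry <- min(mtry, p)
  mns <- params@minNodeSize
  if (is.na(mns)) mns <- if (params@task == "regression") 5L else 10L
  list(mtry = as.integer(mtry), minNodeSize = as.integer(mns))
}

#' Fit a spatial random forest
#'
#' Grows \code{numTrees} trees on (optionally case-weighted) bootstrap
#' draws of the design and keeps the bootstrap and terminal-node
#' bookkeeping needed for quantile-regression-forest weights.
#' Observations with larger case weights are selected with higher
#' probability in the bootstrap; weight-zero observations never enter
#' any tree. More covariates than observations (p >= n) is permitted.
#' Fits are deterministic for a fixed seed.
#'
#' @param design data.frame from \code{\link{buildDesign}} (covariates
#'   plus a \code{y} column).
#' @param params a \linkS4class{ForestParams}.
#' @return An \linkS4class{RFspModel}.
#' @export
fitForest <- function(design, params = forestParams()) {
  methods::validObject(params)
  y <- design$y
  X <- design[, setdiff(names(design), "y"), drop = FALSE]
  if (params@task == "regression") {
    if (!is.numeric(y)) stop("regression task needs a numeric target")
    if (length(unique(y)) < 2L)
      stop("need at least two distinct target values")
  } else {
    y <- as.factor(y)
    if (nlevels(y) < 2L) stop("need at least two classes")
  }
  if (!is.null(params@caseWeights) &&
      length(params@caseWeights) != length(y))
    stop("caseWeights must have one entry per design row")
  rp <- resolve_params(params, ncol(X), nrow(X))
  rf <- ranger::ranger(
    x = X, y = y,
    num.trees = params@numTrees, mtry = rp$mtry,
    min.node.size = rp$minNodeSize,
    sample.fraction = params@sampleFraction, replace = params@replace,
    case.weights = params@caseWeights,
    probability = params@task == "probability",
    importance = "impurity", keep.inbag = TRUE,
    seed = if (is.na(params@seed)) NULL else params@seed,
    num.threads = 1L, oob.error = TRUE)
  trainNodes <- stats::predict(rf, X, type = "terminalNodes",
                               num.threads = 1L)$predictions
  inbag <- do.call(cbind, rf$inbag.counts)
  oobMse <- suppressWarnings(as.numeric(rf$prediction.error))
  if (!is.finite(oobMse)) oobMse <- NA_real_
  oobR2 <- if (params@task == "regression")
    suppressWarnings(as.numeric(rf$r.squared)) else NA_real_
  if (!is.null(oobR2) && !is.finite(oobR2)) oobR2 <- NA_real_
  new("RFspModel", forest = rf, trainY = y,
      trainNodes = trainNodes, inbag = inbag,
      covariateNames = colnames(X), params = params,
      oobMse = oobMse, oobR2 = oobR2,
      importance = rf$variable.importance,
      typeLevels = attr(design, "typeLevels"),
      methodLevels = attr(design, "methodLevels"))
}

check_X0 <- function(model, X0) {
  X0 <- as.data.frame(X0)
  missing <- setdiff(model@covariateNames, names(X0))
  if (length(missing))
    stop("prediction rows lack covariate(s): ",
         paste(missing, collapse = ", "))
  X0[, model@covariateNames, drop = FALSE]
}

#' Mean prediction of a spatial random forest
#'
#' @param model an \linkS4class{RFspModel}.
#' @param X0 covariate rows.
#' @return Numeric predictions (ensemble average over trees).
#' @export
predictMean <- function(model, X0) {
  X0 <- check_X0(model, X0)
  p <- stats::predict(model@forest, X0, num.threads = 1L)$predictions
  if (model@params@task == "probability") p else as.numeric(p)
}

## QRF observation weights alpha_i(s0): per tree, in-bag observations in
## the leaf of s0 get weight proportional to their bootstrap
## multiplicity (normalized within the leaf); weights are then averaged
## over trees. Rows sum to one.
qrf_weights <- function(model, X0) {
  X0 <- check_X0(model, X0)
  predNodes <- stats::predict(model@forest, X0, type = "terminalNodes",
                              num.threads = 1L)$predictions
  n <- nrow(model@trainNodes)
  m <- nrow(X0)
  B <- ncol(model@trainNodes)
  W <- matrix(0, m, n)
  for (b in seq_len(B)) {
    cnt <- model@inbag[, b]
    inb <- which(cnt > 0)
    tn <- model@trainNodes[inb, b]
    tot <- rowsum(cnt[inb], tn)
    wt <- cnt[inb] / tot[as.character(tn), 1L]
    byNode <- split(seq_along(inb), tn)
    prows <- split(seq_len(m), predNodes[, b])
    for (nd in intersect(names(byNode), names(prows))) {
      jj <- inb[byNode[[nd]]]
      W[prows[[nd]], jj] <- W[prows[[nd]], jj] +
        rep(wt[byNode[[nd]]], each = length(prows[[nd]]))
    }
  }
  W / B
}

## Lower-step inversion of a weighted ECDF: smallest observed y with
## cumulative weight >= q. No interpolation between observed values.
weighted_quantile <- function(y, w, qs) {
  ord <- order(y)
  cw <- cumsum(w[ord])
  ys <- y[ord]
  vapply(qs, function(q) ys[which(cw >= q - 1e-12)[1L]], numeric(1))
}

#' Quantile predictions and prediction-error SD from a forest
#'
#' Computes the quantile-regression-forest conditional CDF
#' \code{Fhat(t) = sum_i alpha_i(s0) 1(y_i <= t)} from the forest's leaf
#' weights and inverts it with the lower-step rule (smallest observed y
#' with \code{Fhat >= q}). The conditional mean \code{sum_i alpha_i y_i}
#' and the prediction-error SD \code{sigma = (yhat_0.841 -
#' yhat_0.159) / 2} (half the central 68.27\% interval, assuming
#' symmetric errors) are returned alongside.
#'
#' @param model a regression \linkS4class{RFspModel}.
#' @param X0 covariate rows.
#' @param qs quantile probabilities in (0, 1).
#' @param exposeWeights also return the m x n weight matrix.
#' @return A \linkS4class{QuantilePrediction}.
#' @export
predictQuantiles <- function(model, X0, qs = c(0.159, 0.5, 0.841),
                             exposeWeights = FALSE) {
  if (model@params@task != "regression")
    stop("quantile prediction needs a regression forest")
  if (length(qs) == 0L) stop("qs must not be empty")
  if (any(qs <= 0 | qs >= 1)) stop("qs must lie strictly inside (0, 1)")
  qs <- sort(qs)
  W <- qrf_weights(model, X0)
  y <- as.numeric(model@trainY)
  allq <- sort(unique(c(qs, 0.159, 0.841)))
  V <- t(apply(W, 1, function(w) weighted_quantile(y, w, allq)))
  sigma <- (V[, match(0.841, allq)] - V[, match(0.159, allq)]) / 2
  vals <- V[, match(qs, allq), drop = FALSE]
  colnames(vals) <- paste0("q", qs)
  new("QuantilePrediction", qs = qs, values = vals,
      mean = as.numeric(W %*% y), sigma = as.numeric(sigma),
      weights = if (exposeWeights) W else NULL)
}

#' Prediction-error SD from a central 68.27\% interval
#'
#' \code{sigma = (q841 - q159) / 2}: half the width of the central
#' 68.27\% prediction interval, which equals one SD when the conditional
#' distribution is symmetric (an approximation when it is not).
#'
#' @param q841,q159 the 0.841 and 0.159 conditional quantiles.
#' @return sigma (>= 0).
#' @export
sigmaFromInterval <- function(q841, q159) {
  if (any(q841 < q159)) stop("q841 must be >= q159")
  (q841 - q159) / 2
}

#' Variance of the full QRF conditional distribution
#'
#' Exact second moment of the weighted conditional distribution, an
#' alternative to the symmetric-interval approximation of
#' \code{\link{sigmaFromInterval}}.
#'
#' @param model a regression \linkS4class{RFspModel}.
#' @param X0 covariate rows.
#' @return Conditional SD per row.
#' @export
sigmaFromDistribution <- function(model, X0) {
  W <- qrf_weights(model, X0)
  y <- as.numeric(model@trainY)
  mu <- as.numeric(W %*% y)
  sqrt(pmax(as.numeric(W %*% y^2) - mu^2, 0))
}

#' Per-class probability predictions
#'
#' Ensemble-averaged leaf class frequencies of a probability forest;
#' each row is a probability vector over the classes. For a binary
#' target this is mathematically equivalent to a regression forest on
#' the 0/1 indicator.
#'
#' @param model a probability-mode \linkS4class{RFspModel}.
#' @param X0 covariate rows.
#' @return m x K matrix of class probabilities (rows sum to one).
#' @export
predictProbabilities <- function(model, X0) {
  if (model@params@task != "probability")
    stop("mode error: model was fitted as a regression forest; ",
         "probability prediction needs task = 'probability'")
  X0 <- check_X0(model, X0)
  stats::predict(model@forest, X0, num.threads = 1L)$predictions
}

#' Predict one variable of a multivariate (stacked) model
#'
#' A multivariate model is a single forest fitted on rows of several
#' variables distinguished by 0/1 type (and optionally method)
#' indicators. Predicting variable \code{activeType} with sampling
#' method \code{activeMethod} sets exactly that type indicator (and
#' method indicator) to 1 and all others to 0 across the prediction
#' grid.
#'
#' @param model an \linkS4class{RFspModel} fitted on a multivariate
#'   design.
#' @param stack \linkS4class{CovariateStack} carrying all non-indicator
#'   covariates of the model.
#' @param activeType which variable to map.
#' @param activeMethod which method indicator to set (required when the
#'   model has method indicators).
#' @return A \linkS4class{CovariateStack} with one layer
#'   \code{pred_<activeType>} (masked cells NA-filled as 0 under the
#'   mask).
#' @export
predictMultivariate <- function(model, stack, activeType,
                                activeMethod = NULL) {
  if (is.null(model@typeLevels))
    stop("model was not fitted on a multivariate design")
  if (!activeType %in% model@typeLevels)
    stop("unknown type '", activeType, "'; known types: ",
         paste(model@typeLevels, collapse = ", "))
  if (!is.null(model@methodLevels)) {
    if (is.null(activeMethod))
      stop("model has method indicators; supply activeMethod (one of ",
           paste(model@methodLevels, collapse = ", "), ")")
    if (!activeMethod %in% model@methodLevels)
      stop("unknown method '", activeMethod, "'; known methods: ",
           paste(model@methodLevels, collapse = ", "))
  }
  valid <- mat_to_vec(stack@mask)
  X0 <- as.data.frame(lapply(stack@layers, mat_to_vec))[valid, , drop = FALSE]
  for (lv in model@typeLevels)
    X0[[paste0("TYPE_", lv)]] <- as.numeric(lv == activeType)
  for (lv in model@methodLevels)
    X0[[paste0("METHOD_", lv)]] <- as.numeric(lv == activeMethod)
  pred <- predictMean(model, X0)
  v <- rep(0, length(valid))
  v[valid] <- pred
  out <- stats::setNames(list(vec_to_mat(stack@grid, v)),
                         paste0("pred_", activeType))
  CovariateStack(stack@grid, out, roles = "process", mask = stack@mask)
}
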