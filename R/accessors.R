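## Accessor and show methods.

#' @rdname accessors
setMethod("npoints", "PointSet", function(x) nrow(x@coords))

#' @rdname accessors
setMethod("coords", "PointSet", function(x) x@coords)

#' @rdname accessors
setMethod("targetValues", "PointSet", function(x) x@target)

#' @rdname accessors
setMethod("measurementSd", "PointSet", function(x) x@measSd)

#' @rdname accessors
setMethod("timeValues", "PointSet", function(x) x@time)

#' @rdname accessors
setMethod("typeLabels", "PointSet", function(x) x@typeLabel)

#' @rdname accessors
setMethod("methodLabels", "PointSet", function(x) x@methodLabel)

#' Subset a PointSet
#'
#' @param x a \linkS4class{PointSet}.
#' @param i integer or logical index.
#' @param j,...,drop ignored.
#' @return The subsetted \linkS4class{PointSet}.
#' @export
setMethod("[", "PointSet", function(x, i, j, ..., drop = TRUE) {
  sub <- function(v) if (is.null(v)) NULL else v[i]
  tg <- x@target[i]
  if (is.factor(tg)) tg <- droplevels(tg)
  new("PointSet", ids = x@ids[i], coords = x@coords[i, , drop = FALSE],
      time = sub(x@time), target = tg, measSd = sub(x@measSd),
      typeLabel = sub(x@typeLabel), methodLabel = sub(x@methodLabel))
})

setMethod("show", "PointSet", function(object) {
  kind <- if (is.factor(object@target)) "categorical" else "numeric"
  cat("PointSet with", npoints(object), "points,", kind, "target\n")
  cat("  x range:", paste(signif(range(object@coords[, 1]), 6),
                          collapse = " .. "), "\n")
  cat("  y range:", paste(signif(range(object@coords[, 2]), 6),
                          collapse = " .. "), "\n")
  if (!is.null(object@time))
    cat("  dates:", format(min(object@time)), "..",
        format(max(object@time)), "\n")
  if (!is.null(object@measSd)) cat("  per-point measurement-error SDs\n")
  if (!is.null(object@typeLabel))
    cat("  types:", paste(unique(object@typeLabel), collapse = ", "), "\n")
})

#' @rdname accessors
setMethod("gridSpec", "CovariateStack", function(x) x@grid)

#' @rdname accessors
setMethod("layerNames", "CovariateStack", function(x) names(x@layers))

#' @rdname accessors
setMethod("nLayers", "CovariateStack", function(x) length(x@layers))

#' @rdname accessors
setMethod("getLayer", "CovariateStack", function(x, name) x@layers[[name]])

#' @rdname accessors
setMethod("maskMatrix", "CovariateStack", function(x) x@mask)

#' @rdname accessors
setMethod("layerRoles", "CovariateStack", function(x) x@roles)

#' @rdname accessors
setMethod("sourceIds", "BufferDistanceStack", function(x) x@sourceIds)

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec", object@nrows, "x", object@ncols, "cells, cell size",
      object@cellSize, "\n")
  cat("  origin (left, top):", object@origin[1], object@origin[2],
      " crs:", object@crsTag, "\n")
})

setMethod("show", "CovariateStack", function(object) {
  cat(class(object), "with", nLayers(object), "layer(s) on a",
      object@grid@nrows, "x", object@grid@ncols, "grid\n")
  if (nLayers(object) <= 8)
    cat("  layers:", paste(layerNames(object), collapse = ", "), "\n")
  else
    cat("  layers:", paste(head(layerNames(object), 4), collapse = ", "),
        "...", paste(tail(layerNames(object), 1)), "\n")
  cat(" ", sum(!object@mask), "masked cell(s)\n")
})

#' @rdname accessors
setMethod("nugget", "VariogramModel", function(x) x@nugget)

#' @rdname accessors
setMethod("psill", "VariogramModel", function(x) x@psill)

#' @rdname accessors
setMethod("rangeParam", "VariogramModel", function(x) x@rangeParam)

#' @rdname accessors
setMethod("vgmFamily", "VariogramModel", function(x) x@family)

#' @rdname accessors
setMethod("totalSill", "VariogramModel", function(x) x@nugget + x@psill)

setMethod("show", "VariogramModel", function(object) {
  cat("VariogramModel:", object@family, "\n")
  cat("  nugget tau^2  :", signif(object@nugget, 6), "\n")
  cat("  partial sill  :", signif(object@psill, 6), "\n")
  if (object@family != "pure-nugget") {
    cat("  range phi     :", signif(object@rangeParam, 6), "\n")
    cat("  practical range (cor = 0.05):",
        signif(practicalRange(object), 6), "\n")
  }
})

setMethod("show", "EmpiricalVariogram", function(object) {
  cat("EmpiricalVariogram with", length(object@lag), "populated bins",
      "(max dist", signif(object@maxDist, 6), ")\n")
  print(data.frame(lag = signif(object@lag, 5),
                   gamma = signif(object@gamma, 5),
                   npairs = object@npairs), row.names = FALSE)
})

setMethod("show", "RFspModel", function(object) {
  cat("RFspModel (", object@params@task, ") with ",
      object@params@numTrees, " trees, ",
      length(object@covariateNames), " covariates, n = ",
      length(object@trainY), "\n", sep = "")
  if (!is.na(object@oobMse)) cat("  OOB MSE:", signif(object@oobMse, 6))
  if (!is.na(object@oobR2)) cat("  OOB R2:", signif(object@oobR2, 4))
  cat("\n")
})

#' @rdname accessors
setMethod("oobStats", "RFspModel", function(x)
  list(mse = x@oobMse, r2 = x@oobR2))

#' @rdname accessors
setMethod("cvMetrics", "CVReport", function(x) x@metrics)

setMethod("show", "CVReport", function(object) {
  m <- object@metrics
  cat("CVReport for method '", object@method, "' (",
      length(object@yObs), " held-out points, ",
      length(unique(object@foldOf)), " folds)\n", sep = "")
  cat(sprintf("  RMSE %.5g  ME %.5g  R2 %.4g  CCC %.4g  rho %.4g\n",
              m$rmse, m$me, m$r2, m$ccc, m$rho))
  if (!is.null(m$z_mean) && !is.na(m$z_mean))
    cat(sprintf("  z-scores: mean %.4g  var %.4g\n", m$z_mean, m$z_var))
  if (!is.na(object@structureFraction))
    cat(sprintf("  CV-residual variogram structure fraction: %.3g\n",
                object@structureFraction))
})

setMethod("show", "KrigingResult", function(object) {
  cat("KrigingResult at", length(object@predictions), "locations\n")
  cat("  prediction range:",
      paste(signif(range(object@predictions), 6), collapse = " .. "), "\n")
  cat("  variance range  :",
      paste(signif(range(object@variances), 6), collapse = " .. "), "\n")
})
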