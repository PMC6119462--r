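## Geographical covariates: buffer distances to observation points or
## classes, coordinate layers, temporal covariates, and PCA compression
## of covariate stacks.

#' Buffer-distance layers to each observation point
#'
#' Derives one gridded layer per training point whose cell values are
#' the exact Euclidean distance from the cell center to that point, in
#' coordinate units. These layers are the geographical covariates that
#' let a random forest mimic the proximity information kriging obtains
#' from the variogram. Distances are computed analytically
#' (center-to-point), not by raster growth approximations.
#'
#' At training time, covariate values for the observations themselves
#' are obtained by overlaying the points onto these rasterized layers,
#' so a point's self-distance is the (near-zero) distance to its own
#' cell center rather than exactly zero.
#'
#' @param ps a \linkS4class{PointSet}.
#' @param grid the prediction \linkS4class{GridSpec}.
#' @param cap refuse to build more than this many layers (one per
#'   point). With a large number of training points, per-class distances
#'   (\code{\link{classBufferDistances}}) or distances to 10-15 value
#'   classes keep the covariate count manageable.
#' @return A \linkS4class{BufferDistanceStack} with layers
#'   \code{dp_<id>}, role "geographic".
#' @export
bufferDistances <- function(ps, grid, cap = 1000L) {
  n <- npoints(ps)
  if (n > cap)
    stop("refusing to build ", n, " buffer-distance layers (cap ", cap,
         "); group observations into classes (classBufferDistances) or ",
         "bin the target into 10-15 low..high value classes instead")
  centers <- cellCenters(grid)
  D <- cross_dist(centers, ps@coords)          # (cells x n)
  layers <- lapply(seq_len(n), function(i) vec_to_mat(grid, D[, i]))
  names(layers) <- paste0("dp_", ps@ids)
  new("BufferDistanceStack",
      CovariateStack(grid, layers, roles = "geographic"),
      sourceIds = ps@ids)
}

#' Buffer-distance layers to the nearest observation of each class
#'
#' For a categorical target, derives one layer per class holding the
#' distance from each cell center to the nearest observation of that
#' class (the element-wise minimum of the per-point layers of the
#' class). Classes with zero observations are omitted with a warning.
#'
#' @param ps a \linkS4class{PointSet} with a factor target.
#' @param grid the prediction \linkS4class{GridSpec}.
#' @return A \linkS4class{BufferDistanceStack} with one layer per class.
#' @export
classBufferDistances <- function(ps, grid) {
  if (!is.factor(ps@target))
    stop("classBufferDistances needs a categorical target")
  lv <- levels(ps@target)
  counts <- table(ps@target)
  empty <- lv[counts[lv] == 0 | is.na(counts[lv])]
  if (length(empty)) {
    warning("class(es) with zero observations omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
    lv <- setdiff(lv, empty)
  }
  if (!length(lv)) stop("no class has any observation")
  centers <- cellCenters(grid)
  layers <- lapply(lv, function(cl) {
    pts <- ps@coords[ps@target == cl, , drop = FALSE]
    D <- cross_dist(centers, pts)
    vec_to_mat(grid, do.call(pmin, asplit(D, 2)))
  })
  names(layers) <- paste0("dclass_", lv)
  new("BufferDistanceStack",
      CovariateStack(grid, layers, roles = "geographic"),
      sourceIds = lv)
}

#' Coordinate layers s1 (easting) and s2 (northing)
#'
#' Using coordinates alone as predictors tends to produce blocky
#' artifacts in tree ensembles; they are intended as a supplement to
#' buffer distances, not a replacement.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @return A \linkS4class{CovariateStack} with layers \code{s1},
#'   \code{s2} (role "geographic").
#' @export
coordinateGrids <- function(grid) {
  centers <- cellCenters(grid)
  CovariateStack(grid,
                 list(s1 = vec_to_mat(grid, centers[, 1]),
                      s2 = vec_to_mat(grid, centers[, 2])),
                 roles = "geographic")
}

#' Temporal covariates: cumulative days and day-of-year
#'
#' \code{cdate} counts whole days elapsed since 1970-01-01 and \code{doy}
#' is the day of the year (1..366, actual calendar, so Dec 31 of a leap
#' year is 366). Together they let a forest model long-term trend and
#' seasonality of a spatiotemporal variable.
#'
#' @param dates a \code{Date} vector or ISO-8601 strings.
#' @return data.frame with columns \code{cdate} and \code{doy}.
#' @export
temporalCovariates <- function(dates) {
  d <- tryCatch(as.Date(dates), error = function(e) NULL)
  if (is.null(d) || anyNA(d)) {
    bad <- if (is.null(d)) seq_along(dates) else which(is.na(d))
    stop("unparseable date at record(s): ", paste(bad, collapse = ", "))
  }
  data.frame(cdate = as.numeric(d),
             doy = as.POSIXlt(d)$yday + 1L)
}

#' Principal-component compression of a covariate stack
#'
#' Converts possibly collinear covariate layers into orthogonal
#' principal-component layers, computed on centered, unit-variance layer
#' values over the valid (unmasked) cells. Constant layers are dropped
#' with a warning before the decomposition. For deterministic output
#' each component is oriented so its largest-magnitude loading is
#' positive.
#'
#' @param stack a \linkS4class{CovariateStack} with >= 2 layers
#'   (categorical layers already expanded to indicators).
#' @param nComponents how many components to keep (default all).
#' @return list with \code{stack} (PC layers, role "process"),
#'   \code{loadings}, \code{explained} (variance fractions of all
#'   components, summing to one) and \code{dropped}.
#' @export
pcaCovariates <- function(stack, nComponents = NULL) {
  if (nLayers(stack) < 2L) stop("need at least two layers for PCA")
  valid <- which(mat_to_vec(stack@mask))
  X <- sapply(stack@layers, function(l) mat_to_vec(l)[valid])
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("constant layer(s) dropped before PCA: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2L) stop("fewer than two non-constant layers")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  k <- if (is.null(nComponents)) ncol(pc$x) else min(nComponents, ncol(pc$x))
  layers <- lapply(seq_len(k), function(j) {
    v <- rep(NA_real_, stack@grid@nrows * stack@grid@ncols)
    v[valid] <- pc$x[, j]
    m <- vec_to_mat(stack@grid, v)
    m[is.na(m)] <- 0
    m
  })
  names(layers) <- paste0("PC", seq_len(k))
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(stack = CovariateStack(stack@grid, layers, roles = "process",
                              mask = stack@mask),
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = explained, dropped = dropped)
}
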