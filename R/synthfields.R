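## Download-free synthetic data: unconditional Gaussian random fields
## with known variograms, sampling designs, heteroscedastic two-source
## samples, multinomial class maps and zero-inflated seasonal space-time
## fields. All generators are pure functions of (spec, seed).

MAX_DENSE_CELLS <- 6000L

## Simulate a zero-mean Gaussian vector with covariance psill*rho(D)
## plus iid nugget noise, by dense Cholesky factorization (exact for
## any valid covariance at desk scale). A jitter of 1e-10 * sill is
## added to the diagonal before factorization.
grf_draw <- function(coordsMat, vgm, nDraws = 1L) {
  m <- nrow(coordsMat)
  if (vgm@psill > 0) {
    D <- cross_dist(coordsMat, coordsMat)
    Sigma <- vgm@psill * vgm_rho(vgm@family, D, vgm@rangeParam)
    diag(Sigma) <- diag(Sigma) + 1e-10 * max(totalSill(vgm), 1)
    L <- tryCatch(chol(Sigma), error = function(e)
      stop("covariance matrix not positive definite after jitter: ",
           conditionMessage(e), call. = FALSE))
    smooth <- crossprod(L, matrix(stats::rnorm(m * nDraws), m, nDraws))
  } else {
    smooth <- matrix(0, m, nDraws)
  }
  smooth + sqrt(vgm@nugget) * matrix(stats::rnorm(m * nDraws), m, nDraws)
}

#' Simulate a Gaussian random field on a grid
#'
#' Unconditional simulation with the covariance implied by
#' \code{spec@vgm}: a smooth component with covariance
#' \code{psill * rho(h/phi)} drawn by dense Cholesky factorization over
#' the cell centers, plus iid nugget noise. An optional linear trend in
#' supplied covariate layers and an optional \code{exp} transform
#' (yielding a lognormal, skewed field) are applied afterwards.
#' Deterministic given the spec's seed.
#'
#' @param spec a \linkS4class{FieldSpec} (grid of at most ~6000 cells
#'   for the dense factorization).
#' @return A \linkS4class{CovariateStack} with one layer \code{sim}.
#' @export
simulateGRF <- function(spec) {
  grid <- spec@grid
  m <- grid@nrows * grid@ncols
  if (m > MAX_DENSE_CELLS)
    stop("grid has ", m, " cells; dense simulation is capped at ",
         MAX_DENSE_CELLS)
  centers <- cellCenters(grid)
  v <- with_seed(spec@seed, as.numeric(grf_draw(centers, spec@vgm)))
  if (!is.null(spec@trend)) {
    tr <- spec@trend
    if (!is.null(tr$intercept)) v <- v + tr$intercept
    if (!is.null(tr$beta)) {
      for (nm in names(tr$beta))
        v <- v + tr$beta[[nm]] * mat_to_vec(getLayer(tr$stack, nm))
    }
  }
  if (spec@transform == "exp") v <- exp(v)
  CovariateStack(grid, list(sim = vec_to_mat(grid, v)), roles = "process")
}

#' Draw sampling locations on a grid
#'
#' \code{uniform} draws cells uniformly (without replacement by
#' default, avoiding exact-duplicate coordinates); \code{clustered}
#' draws a parent-offspring process: parent cells uniform, offspring
#' scattered around a random parent with Gaussian displacement of SD
#' \code{clusterRadius / 2} (so about 86 percent of points fall within
#' \code{clusterRadius} of their parent), clipped to the extent.
#' Deterministic per seed. Points are placed at cell centers.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param n number of locations.
#' @param design "uniform" or "clustered".
#' @param seed RNG seed.
#' @param replace sample cells with replacement?
#' @param nClusters,clusterRadius clustered-design parameters.
#' @return n x 2 matrix of coordinates, with cell indices in
#'   \code{attr(, "cells")}.
#' @export
sampleDesign <- function(grid, n, design = c("uniform", "clustered"),
                         seed = 1L, replace = FALSE,
                         nClusters = max(1L, round(n / 10)),
                         clusterRadius = 3 * grid@cellSize) {
  design <- match.arg(design)
  m <- grid@nrows * grid@ncols
  if (!replace && n > m)
    stop("cannot draw ", n, " distinct cells from a grid of ", m)
  centers <- cellCenters(grid)
  cells <- with_seed(seed, {
    if (design == "uniform") {
      sample.int(m, n, replace = replace)
    } else {
      parents <- sample.int(m, nClusters, replace = TRUE)
      px <- centers[parents, , drop = FALSE]
      pick <- sample.int(nClusters, n, replace = TRUE)
      xy <- px[pick, , drop = FALSE] +
        matrix(stats::rnorm(2 * n, sd = clusterRadius / 2), n, 2)
      xy[, 1] <- pmin(pmax(xy[, 1], grid@origin[1] + grid@cellSize / 2),
                      grid@origin[1] + (grid@ncols - 0.5) * grid@cellSize)
      xy[, 2] <- pmin(pmax(xy[, 2],
                           grid@origin[2] - (grid@nrows - 0.5) * grid@cellSize),
                      grid@origin[2] - grid@cellSize / 2)
      idx <- cellIndex(grid, xy)
      cl <- (idx$row - 1L) * grid@ncols + idx$col
      attr(cl, "parents") <- parents
      cl
    }
  })
  out <- centers[cells, , drop = FALSE]
  attr(out, "cells") <- as.integer(cells)
  if (!is.null(attr(cells, "parents")))
    attr(out, "parents") <- centers[attr(cells, "parents"), , drop = FALSE]
  out
}

#' Sample a simulated field into a (possibly noisy) PointSet
#'
#' Reads the field value in the cell containing each location and adds
#' zero-mean Gaussian measurement noise. Several noise sources with
#' different SDs model surveys that mix accurate and inaccurate
#' observation methods; each point's generating SD is recorded
#' truthfully in \code{measSd} (omitted when all SDs are zero).
#'
#' @param field a \linkS4class{CovariateStack} whose first layer is the
#'   truth, or a plain matrix plus \code{grid}.
#' @param locations n x 2 coordinate matrix.
#' @param noiseSd per-source noise SDs (>= 0).
#' @param sourceFractions fractions of points per source (sum to 1);
#'   default equal.
#' @param seed RNG seed.
#' @param grid needed for a plain matrix field.
#' @return A \linkS4class{PointSet}; attributes \code{trueValue} and
#'   \code{source}.
#' @export
makeDataset <- function(field, locations, noiseSd = 0,
                        sourceFractions = NULL, seed = 1L, grid = NULL) {
  if (methods::is(field, "CovariateStack")) {
    grid <- field@grid
    layer <- field@layers[[1]]
  } else layer <- field
  if (any(noiseSd < 0)) stop("noise SDs must be non-negative")
  nSrc <- length(noiseSd)
  if (is.null(sourceFractions)) sourceFractions <- rep(1 / nSrc, nSrc)
  if (abs(sum(sourceFractions) - 1) > 1e-8)
    stop("sourceFractions must sum to 1")
  locations <- as.matrix(locations)
  n <- nrow(locations)
  idx <- cellIndex(grid, locations)
  if (any(!idx$inside)) stop("sampling locations outside the grid")
  truth <- layer[cbind(idx$row, idx$col)]
  counts <- diff(round(cumsum(c(0, sourceFractions)) * n))
  source <- rep(seq_len(nSrc), times = counts)
  if (length(source) < n) source <- c(source, rep(nSrc, n - length(source)))
  y <- with_seed(seed, truth + stats::rnorm(n, sd = noiseSd[source]))
  ps <- PointSet(locations, y,
                 measSd = if (all(noiseSd == 0)) NULL else {
                   sd <- noiseSd[source]
                   if (any(sd == 0)) NULL else sd
                 })
  attr(ps, "trueValue") <- truth
  attr(ps, "source") <- source
  ps
}

#' Synthetic multinomial class map with sampled observations
#'
#' Draws K independent latent Gaussian random fields and assigns each
#' cell the class of the maximal latent (a standard construction for
#' spatially coherent categorical maps). Errors out when the parameters
#' collapse the map to a single class.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param K number of classes (>= 2).
#' @param vgm latent-field variogram.
#' @param seed RNG seed.
#' @param n number of observation points to sample (0 for map only).
#' @param design passed to \code{\link{sampleDesign}}.
#' @return list(points, classMap (integer matrix of class codes),
#'   levels, latents (list of K matrices)).
#' @export
makeCategorical <- function(grid, K = 4L, vgm = variogramModel("exponential",
                                                               nugget = 0.05,
                                                               psill = 1,
                                                               rangeParam = 8),
                            seed = 1L, n = 100L,
                            design = "uniform") {
  if (K < 2L) stop("K must be at least 2")
  m <- grid@nrows * grid@ncols
  if (m > MAX_DENSE_CELLS) stop("grid too large for dense simulation")
  centers <- cellCenters(grid)
  Z <- with_seed(seed, grf_draw(centers, vgm, nDraws = K))
  cls <- max.col(Z, ties.method = "first")
  if (length(unique(cls)) < 2L)
    stop("latent fields collapsed to a single class; ",
         "increase the partial sill or shorten the range")
  levels <- paste0("class", seq_len(K))
  points <- NULL
  if (n > 0) {
    loc <- sampleDesign(grid, n, design = design, seed = seed + 1L)
    cells <- attr(loc, "cells")
    points <- PointSet(loc, factor(levels[cls[cells]], levels = levels))
  }
  list(points = points,
       classMap = vec_to_mat(grid, cls),
       levels = levels,
       latents = lapply(seq_len(K), function(k) vec_to_mat(grid, Z[, k])))
}

#' Synthetic zero-inflated seasonal space-time observations
#'
#' Daily station data generated as seasonal mean (a cosine in
#' day-of-year peaking at \code{seasonalPhase}) plus an AR(1)-evolving
#' spatial Gaussian field (stationary marginal: \code{f_t = a f_(t-1) +
#' sqrt(1 - a^2) e_t}) plus iid nugget noise, then left-censored: latent
#' values at or below \code{zeroThreshold} become exact zeros, emulating
#' zero-inflated daily precipitation. Stations are fixed across days.
#'
#' @param spec a \linkS4class{SpaceTimeSpec}.
#' @param nDays number of consecutive days (>= 2).
#' @param nStations number of stations.
#' @param grid station-sampling grid.
#' @param startDate first day.
#' @return list(points (stacked station-day \linkS4class{PointSet} with
#'   dates), stations, dates, latent (nStations x nDays matrix)).
#' @export
makeSpacetime <- function(spec, nDays, nStations,
                          grid = GridSpec(20, 20, cellSize = 1),
                          startDate = "2014-01-01") {
  methods::validObject(spec)
  if (nDays < 2L) stop("nDays must be at least 2")
  stations <- sampleDesign(grid, nStations, seed = spec@seed)
  dates <- seq(as.Date(startDate), by = "day", length.out = nDays)
  doy <- as.POSIXlt(dates)$yday + 1
  seasonal <- spec@meanLevel + spec@seasonalAmplitude *
    cos(2 * pi * (doy - spec@seasonalPhase) / 365.25)
  a <- spec@temporalCorr
  vg <- spec@spatialVgm
  smoothVgm <- variogramModel(vg@family, nugget = 0, psill = vg@psill,
                              rangeParam = vg@rangeParam)
  latent <- with_seed(spec@seed + 1L, {
    eps <- grf_draw(stations, smoothVgm, nDraws = nDays)
    f <- matrix(0, nStations, nDays)
    f[, 1] <- eps[, 1]
    for (t in seq_len(nDays - 1L) + 1L)
      f[, t] <- a * f[, t - 1L] + sqrt(1 - a^2) * eps[, t]
    nug <- matrix(stats::rnorm(nStations * nDays, sd = sqrt(vg@nugget)),
                  nStations, nDays)
    sweep(f + nug, 2, seasonal, "+")
  })
  y <- ifelse(latent <= spec@zeroThreshold, 0, latent)
  ps <- suppressWarnings(PointSet(
    stations[rep(seq_len(nStations), times = nDays), ],
    as.numeric(y),
    ids = paste0("st", rep(seq_len(nStations), times = nDays),
                 "_d", rep(seq_len(nDays), each = nStations)),
    time = rep(dates, each = nStations)))
  list(points = ps, stations = stations, dates = dates, latent = latent)
}
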