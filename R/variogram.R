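## Variograms: Box-Cox transforms, the method-of-moments estimator and
## weighted-least-squares model fitting.

#' Box-Cox transformation and its inverse
#'
#' \code{boxcox} maps positive data to \code{(y^eta - 1)/eta} for
#' \code{eta != 0} and to \code{log(y)} for \code{eta = 0};
#' \code{boxcoxInverse} is the exact algebraic inverse.
#'
#' @param y positive values (forward); transformed values (inverse).
#' @param eta transformation exponent.
#' @return Transformed (or back-transformed) values.
#' @export
boxcox <- function(y, eta) {
  if (eta <= 0 && any(y <= 0))
    stop("Box-Cox with eta <= 0 requires strictly positive data")
  if (eta == 0) log(y) else (y^eta - 1) / eta
}

#' @rdname boxcox
#' @export
boxcoxInverse <- function(y, eta) {
  if (eta == 0) exp(y) else (eta * y + 1)^(1 / eta)
}

## correlation function rho(h; phi) per family
vgm_rho <- function(family, h, phi) {
  switch(family,
    "exponential" = exp(-h / phi),
    "gaussian" = exp(-(h / phi)^2),
    "spherical" = {
      u <- pmin(h / phi, 1)
      1 - 1.5 * u + 0.5 * u^3
    },
    "pure-nugget" = ifelse(h == 0, 1, 0) * 0,
    stop("unknown family: ", family))
}

#' Semivariance and covariance of a variogram model
#'
#' \code{semivariance} returns \code{gamma(h) = tau^2 * 1(h > 0) +
#' sigma_p^2 * (1 - rho(h/phi))}; \code{vgmCovariance} returns
#' \code{C(h) = sigma_p^2 * rho(h/phi) + tau^2 * 1(h == 0)}, so the two
#' sum to the total sill for every h > 0.
#'
#' @param vgm a \linkS4class{VariogramModel}.
#' @param h distances (>= 0).
#' @return Numeric vector like \code{h}.
#' @export
semivariance <- function(vgm, h) {
  vgm@nugget * (h > 0) + vgm@psill * (1 - vgm_rho(vgm@family, h, vgm@rangeParam))
}

#' @rdname semivariance
#' @export
vgmCovariance <- function(vgm, h) {
  vgm@psill * vgm_rho(vgm@family, h, vgm@rangeParam) + vgm@nugget * (h == 0)
}

#' @rdname accessors
#' @export
setMethod("practicalRange", "VariogramModel", function(x) {
  if (x@family == "pure-nugget" || x@psill == 0) return(0)
  f <- function(h) vgm_rho(x@family, h, x@rangeParam) - 0.05
  upper <- x@rangeParam
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(1e-12 * x@rangeParam, upper), tol = 1e-10)$root
})

#' Method-of-moments (Matheron) sample variogram
#'
#' Bins all point pairs by separation distance and estimates the
#' semivariance per bin as \code{sum (y_i - y_j)^2 / (2 N(h))}. Bin
#' centers are the mean pair distance per bin; empty bins are dropped.
#'
#' @param ps a \linkS4class{PointSet} with a numeric target (n >= 2).
#' @param nBins number of equal-width distance bins.
#' @param maxDist pairs farther apart are ignored; defaults to half the
#'   maximum pairwise distance.
#' @return An \linkS4class{EmpiricalVariogram}.
#' @export
empiricalVariogram <- function(ps, nBins = 15L, maxDist = NULL) {
  if (!is.numeric(ps@target)) stop("empirical variogram needs numeric targets")
  n <- npoints(ps)
  if (n < 2L) stop("need at least two points")
  d <- stats::dist(ps@coords)
  g <- stats::dist(as.numeric(ps@target))^2 / 2
  if (max(d) == 0) stop("all points coincide; no variogram is estimable")
  if (is.null(maxDist)) maxDist <- max(d) / 2
  keep <- d <= maxDist & d > 0
  if (!any(keep)) {
    keep <- d > 0
    maxDist <- max(d)
  }
  d <- as.numeric(d[keep]); g <- as.numeric(g[keep])
  if (length(unique(d)) == 1L) {
    warning("all pair distances identical; returning a single bin",
            call. = FALSE)
    return(new("EmpiricalVariogram", lag = d[1], gamma = mean(g),
               npairs = as.numeric(length(g)), maxDist = maxDist,
               nBins = 1L))
  }
  breaks <- seq(0, maxDist, length.out = nBins + 1L)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE, left.open = TRUE)
  lag <- tapply(d, bin, mean)
  gamma <- tapply(g, bin, mean)
  npairs <- tapply(g, bin, length)
  ord <- order(lag)
  new("EmpiricalVariogram", lag = as.numeric(lag[ord]),
      gamma = as.numeric(gamma[ord]), npairs = as.numeric(npairs[ord]),
      maxDist = maxDist, nBins = as.integer(nBins))
}

#' Fit a variogram model by weighted least squares
#'
#' Minimizes \code{sum N(h) / gamma_model(h)^2 * (gamma_hat(h) -
#' gamma_model(h))^2} over (nugget, partial sill, range) with
#' non-negativity bounds, from a deterministic set of data-driven
#' starting values. If every start fails the fit falls back to a
#' pure-nugget model with a warning.
#'
#' @param emp an \linkS4class{EmpiricalVariogram} with >= 3 populated
#'   bins.
#' @param family correlation family to fit.
#' @param initial optional numeric c(nugget, psill, range) start.
#' @return A \linkS4class{VariogramModel}.
#' @export
fitVariogram <- function(emp, family = c("exponential", "spherical",
                                         "gaussian", "pure-nugget"),
                         initial = NULL) {
  family <- match.arg(family)
  lag <- emp@lag; gh <- emp@gamma; np <- emp@npairs
  if (family == "pure-nugget")
    return(variogramModel("pure-nugget",
                          nugget = sum(np * gh) / sum(np), psill = 0))
  if (length(lag) < 3L)
    stop("need at least three populated bins to fit a ", family, " model")
  obj <- function(par) {
    g <- par[1] * (lag > 0) + par[2] * (1 - vgm_rho(family, lag, par[3]))
    sum(np / pmax(g, 1e-12)^2 * (gh - g)^2)
  }
  vtot <- max(gh)
  maxd <- max(lag)
  starts <- list(c(0, vtot, maxd / 3), c(vtot / 2, vtot / 2, maxd / 3),
                 c(0, vtot, maxd / 10), c(vtot / 10, vtot, maxd),
                 c(vtot / 2, vtot / 2, maxd / 20))
  if (!is.null(initial)) starts <- c(list(as.numeric(initial)), starts)
  ## the range is not identifiable beyond the observed lags; cap it
  lower <- c(0, 1e-12 * vtot, 1e-6 * maxd)
  upper <- c(5 * vtot, 10 * vtot, 3 * maxd)
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e3,
                                  parscale = pmax(abs(s), c(vtot, vtot, maxd))
                                             / 10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) {
    warning("variogram optimization failed on all starts; ",
            "falling back to pure nugget", call. = FALSE)
    return(variogramModel("pure-nugget",
                          nugget = sum(np * gh) / sum(np), psill = 0))
  }
  variogramModel(family, nugget = best$par[1], psill = best$par[2],
                 rangeParam = best$par[3])
}

#' Serialize / deserialize a variogram model as JSON
#'
#' @param vgm a \linkS4class{VariogramModel}.
#' @param path JSON file.
#' @return \code{path} (write) or a \linkS4class{VariogramModel} (read).
#' @export
writeVariogram <- function(vgm, path) {
  jsonlite::write_json(list(family = vgm@family, nugget = vgm@nugget,
                            psill = vgm@psill, range = vgm@rangeParam,
                            eta = vgm@eta),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeVariogram
#' @export
readVariogram <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  variogramModel(x$family, nugget = x$nugget, psill = x$psill,
                 rangeParam = x$range, eta = x$eta)
}
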