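test_that("Box-Cox branches and round trip", {
  expect_equal(boxcox(exp(1), 0), 1)
  expect_equal(boxcox(5, 1), 4)
  expect_error(boxcox(c(1, -2), 0), "positive")
  set.seed(8)
  y <- rexp(1000) + 1e-3
  for (eta in c(-0.5, 0, 0.5, 1))
    expect_equal(boxcoxInverse(boxcox(y, eta), eta), y, tolerance = 1e-12)
})

test_that("variogram model algebra: gamma + C = sill, practical range", {
  for (fam in c("exponential", "spherical", "gaussian")) {
    vg <- variogramModel(fam, nugget = 0.3, psill = 1.7, rangeParam = 4)
    h <- c(0.5, 1, 3, 7, 20)
    expect_equal(semivariance(vg, h) + vgmCovariance(vg, h),
                 rep(totalSill(vg), 5))
    expect_equal(vgmCovariance(vg, 0), totalSill(vg))
    pr <- practicalRange(vg)
    expect_equal(vgmCovariance(vg, pr) / psill(vg), 0.05, tolerance = 1e-6)
  }
  expect_equal(practicalRange(variogramModel("exponential", 0, 1, 2)),
               2 * log(20), tolerance = 1e-6)
})

test_that("two-point and constant-field variograms by hand", {
  ps <- PointSet(rbind(c(0, 0), c(1, 0)), c(0, 2))
  expect_warning(emp <- empiricalVariogram(ps, maxDist = 2), "single bin")
  expect_equal(length(emp@lag), 1L)
  expect_equal(emp@gamma, 2)          # (0-2)^2 / 2
  set.seed(1)
  cst <- PointSet(cbind(runif(30), runif(30)), rep(7, 30))
  expect_true(all(empiricalVariogram(cst)@gamma == 0))
})

test_that("every variogram bin equals a brute-force all-pairs loop", {
  set.seed(33)
  n <- 100
  ps <- PointSet(cbind(runif(n, 0, 50), runif(n, 0, 50)), rnorm(n))
  nBins <- 10
  emp <- empiricalVariogram(ps, nBins = nBins)
  ## independent double loop
  xy <- coords(ps); y <- as.numeric(targetValues(ps))
  maxd <- emp@maxDist
  breaks <- seq(0, maxd, length.out = nBins + 1)
  sums <- cnts <- dsum <- numeric(nBins)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    if (d > 0 && d <= maxd) {
      b <- max(1, ceiling(d / (maxd / nBins)))
      sums[b] <- sums[b] + (y[i] - y[j])^2
      cnts[b] <- cnts[b] + 1
      dsum[b] <- dsum[b] + d
    }
  }
  keep <- cnts > 0
  expect_equal(emp@npairs, cnts[keep])
  expect_equal(emp@gamma, (sums / (2 * cnts))[keep])
  expect_equal(emp@lag, (dsum / cnts)[keep])
})

test_that("noise-free exponential variograms are recovered sharply", {
  true <- exp_vgm(nugget = 0.4, psill = 2, range = 6)
  lag <- seq(1, 25, length.out = 14)
  emp <- new("EmpiricalVariogram", lag = lag, gamma = semivariance(true, lag),
             npairs = rep(100, 14), maxDist = 25, nBins = 14L)
  fit <- fitVariogram(emp, "exponential")
  expect_equal(nugget(fit), 0.4, tolerance = 1e-4)
  expect_equal(psill(fit), 2, tolerance = 1e-4)
  expect_equal(rangeParam(fit), 6, tolerance = 1e-4)
})

test_that("white-noise data fit to a near-pure-nugget model", {
  sf <- sapply(1:20, function(r) {
    set.seed(1000 + r)
    ps <- PointSet(cbind(runif(200, 0, 40), runif(200, 0, 40)), rnorm(200))
    residualAutocorrelation(ps)$structure_fraction
  })
  ## spatially structured share is small for iid data
  expect_lt(median(sf), 0.1)
})

test_that("ordinary kriging interpolates exactly with zero nugget", {
  dat <- grf_points(n = 25, vgm = exp_vgm(nugget = 0, psill = 1.3, range = 4),
                    seed = 5)
  kr <- okPredict(dat$ps, coords(dat$ps), exp_vgm(0, 1.3, 4))
  expect_lt(max(abs(kr@predictions - as.numeric(targetValues(dat$ps)))), 1e-6)
  expect_lt(max(kr@variances), 1e-6)
})

test_that("kriging weights always sum to one", {
  dat <- grf_points(n = 30, seed = 6)
  tg <- cbind(runif(12, 0, 20), runif(12, 0, 20))
  kr <- okPredict(dat$ps, tg, exp_vgm(), keepWeights = TRUE)
  expect_true(all(abs(colSums(kr@weights) - 1) < 1e-10))
  expect_true(all(kr@variances >= 0))
})

test_that("okPredict matches an independent gamma-form dense solve", {
  set.seed(77)
  vg <- exp_vgm(nugget = 0.2, psill = 1, range = 3)
  for (r in 1:10) {
    n <- sample(3:10, 1)
    xy <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    y <- rnorm(n)
    tg <- cbind(runif(3, 0, 10), runif(3, 0, 10))
    kr <- okPredict(PointSet(xy, y), tg, vg)
    ## oracle: semivariogram formulation of the OK system
    G <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      G[i, j] <- semivariance(vg, sqrt(sum((xy[i, ] - xy[j, ])^2)))
    A <- rbind(cbind(G, 1), c(rep(1, n), 0))
    for (t in 1:3) {
      g0 <- sapply(1:n, function(i)
        semivariance(vg, sqrt(sum((xy[i, ] - tg[t, ])^2))))
      sol <- solve(A, c(g0, 1))
      w <- sol[1:n]; phi <- sol[n + 1]
      expect_equal(kr@predictions[t], sum(w * y), tolerance = 1e-8)
      expect_equal(kr@variances[t], sum(w * g0) + phi, tolerance = 1e-8)
    }
  }
})

test_that("duplicates with zero nugget are refused by name", {
  ps <- suppressWarnings(PointSet(rbind(c(1, 1), c(1, 1), c(2, 2)), 1:3,
                                  ids = c("a", "b", "c")))
  expect_error(okPredict(ps, cbind(1.5, 1.5), exp_vgm(nugget = 0)), "a, b")
  ## positive nugget makes the same configuration solvable
  kr <- okPredict(ps, cbind(1.5, 1.5), exp_vgm(nugget = 0.5))
  expect_true(is.finite(kr@predictions))
})

test_that("pure-nugget kriging collapses to the sample mean", {
  dat <- grf_points(n = 40, seed = 9)
  vg <- variogramModel("pure-nugget", nugget = 1, psill = 0)
  kr <- okPredict(dat$ps, cbind(c(3.3, 11.1), c(4.4, 17.2)), vg)
  expect_equal(kr@predictions,
               rep(mean(as.numeric(targetValues(dat$ps))), 2),
               tolerance = 1e-8)
})

test_that("far-away observations are screened out", {
  set.seed(12)
  xy <- cbind(runif(20, 0, 10), runif(20, 0, 10))
  y <- rnorm(20)
  vg <- exp_vgm(nugget = 0.1, psill = 1, range = 2)   # practical range ~6
  tg <- cbind(5, 5)
  ## nearest-m neighborhoods screen distant observations out entirely
  base <- okPredict(PointSet(xy, y), tg, vg, nmax = 20)@predictions
  far <- okPredict(PointSet(rbind(xy, c(1e5, 1e5)), c(y, 100)), tg,
                   vg, nmax = 20)@predictions
  expect_lt(abs(base - far), 1e-6)
  ## globally, an uncorrelated point only enters through the mean share
  farGlob <- okPredict(PointSet(rbind(xy, c(1e5, 1e5)), c(y, 0)), tg,
                       vg)@predictions
  expect_lt(abs(base - farGlob), 0.5)
})

test_that("local neighborhoods approximate the global solve", {
  dat <- grf_points(n = 50, seed = 14)
  tg <- cellCenters(dat$grid)[c(40, 200, 360), ]
  glob <- okPredict(dat$ps, tg, exp_vgm())
  loc <- okPredict(dat$ps, tg, exp_vgm(), nmax = 30)
  expect_equal(loc@predictions, glob@predictions, tolerance = 0.05)
})

test_that("lognormal back-transform matches the closed-form moments", {
  bt <- lognormalBacktransform(0, 1)
  expect_equal(bt$prediction, exp(0.5), tolerance = 1e-12)
  expect_equal(bt$variance, exp(1) * (exp(1) - 1), tolerance = 1e-12)
  expect_equal(lognormalBacktransform(2, 0)$prediction, exp(2))
  expect_equal(lognormalBacktransform(2, 0)$variance, 0)
})

test_that("trend model: exact fits, leverage and the normal equations", {
  set.seed(20)
  X <- data.frame(a = rnorm(40), b = rnorm(40))
  y <- 2 + 3 * X$a - 1.5 * X$b
  tm <- fitTrend(X, y)
  expect_equal(unname(tm@beta), c(2, 3, -1.5), tolerance = 1e-10)
  expect_lt(tm@mse, 1e-20)
  pr <- predictTrend(tm, data.frame(a = c(0, 5), b = c(0, -5)))
  expect_lt(max(pr$variance), 1e-18)

  ## noisy fit equals an independent normal-equations solve
  y2 <- y + rnorm(40)
  tm2 <- fitTrend(X, y2)
  Xd <- cbind(1, as.matrix(X))
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y2)
  expect_equal(unname(tm2@beta), as.numeric(beta), tolerance = 1e-10)
  ## prediction variance is smallest at the covariate mean
  vMean <- predictTrend(tm2, data.frame(a = mean(X$a), b = mean(X$b)))$variance
  vEdge <- predictTrend(tm2, data.frame(a = max(X$a) + 3, b = min(X$b) - 3))$variance
  expect_lt(vMean, vEdge)
  expect_equal(vMean, tm2@mse * (1 + t(c(1, mean(X$a), mean(X$b))) %*%
               solve(t(Xd) %*% Xd) %*% c(1, mean(X$a), mean(X$b)))[1],
               tolerance = 1e-10)
})

test_that("n <= p directs users to the forest module", {
  X <- data.frame(a = rnorm(3), b = rnorm(3), c = rnorm(3))
  expect_error(fitTrend(X, rnorm(3)), "fitForest")
})

test_that("rank-deficient designs drop columns with a warning", {
  set.seed(2)
  X <- data.frame(a = rnorm(20))
  X$b <- 2 * X$a
  expect_warning(tm <- fitTrend(X, rnorm(20)), "dropped")
  expect_equal(tm@p, 2L)
})

test_that("RK equals MLR under a pure-nugget residual model", {
  grid <- tiny_grid(10, 10)
  set.seed(30)
  covStack <- CovariateStack(grid, list(z = matrix(rnorm(100), 10, 10)))
  loc <- sampleDesign(grid, 40, seed = 31)
  zAt <- overlayPoints(PointSet(loc, rep(0, 40)), covStack)$z
  y <- 1 + 2 * zAt + rnorm(40, sd = 0.3)
  ps <- PointSet(loc, y)
  ## target cells that carry no observation (pure-nugget kriging at a
  ## data location would reproduce that residual instead of the mean)
  free <- setdiff(seq_len(100), attr(loc, "cells"))
  tg <- cellCenters(grid)[free[1:3], ]
  nugg <- variogramModel("pure-nugget", nugget = 0.09, psill = 0)
  rk <- rkPredict(ps, covStack, targets = tg, residVgm = nugg)
  tm <- fitTrend(overlayPoints(ps, covStack), y)
  X0 <- overlayPoints(PointSet(tg, rep(0, 3)), covStack)
  expect_equal(rk@predictions, predictTrend(tm, X0)$prediction,
               tolerance = 1e-8)
})

test_that("RK with an intercept-only trend reproduces OK exactly", {
  dat <- grf_points(n = 35, seed = 40)
  const <- CovariateStack(dat$grid, list(k = matrix(1, 20, 20)))
  tg <- cellCenters(dat$grid)[c(10, 100, 390), ]
  vg <- exp_vgm()
  rk <- suppressWarnings(rkPredict(dat$ps, const, targets = tg, residVgm = vg))
  ok <- okPredict(dat$ps, tg, vg)
  expect_equal(rk@predictions, ok@predictions, tolerance = 1e-8)
})

test_that("a 5-point RK run equals the hand-composed pipeline", {
  grid <- tiny_grid(6, 6)
  set.seed(50)
  covStack <- CovariateStack(grid, list(z = matrix(rnorm(36), 6, 6)))
  loc <- cellCenters(grid)[c(2, 9, 16, 23, 30), ]
  zAt <- overlayPoints(PointSet(loc, rep(0, 5)), covStack)$z
  y <- 0.5 + 1.2 * zAt + rnorm(5, sd = 0.5)
  ps <- PointSet(loc, y)
  tg <- cellCenters(grid)[c(6, 31), ]
  vg <- exp_vgm(nugget = 0.1, psill = 0.4, range = 2)
  rk <- rkPredict(ps, covStack, targets = tg, residVgm = vg)
  ## steps 1-7 by hand
  fit <- lm(y ~ zAt)
  resid <- as.numeric(residuals(fit))
  z0 <- overlayPoints(PointSet(tg, c(0, 0)), covStack)$z
  trend <- coef(fit)[1] + coef(fit)[2] * z0
  krig <- okPredict(PointSet(loc, resid), tg, vg)
  expect_equal(rk@predictions, unname(trend + krig@predictions),
               tolerance = 1e-10)
})

test_that("variogram JSON round-trips", {
  vg <- variogramModel("spherical", nugget = 0.123456789, psill = 4.5,
                       rangeParam = 321.0987)
  f <- tempfile(fileext = ".json")
  writeVariogram(vg, f)
  back <- readVariogram(f)
  expect_equal(nugget(back), nugget(vg))
  expect_equal(psill(back), psill(vg))
  expect_equal(rangeParam(back), rangeParam(vg))
  expect_identical(vgmFamily(back), "spherical")
})
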