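test_that("the design table matches the overlay oracle", {
  dat <- grf_points(n = 30, seed = 61)
  bufs <- bufferDistances(dat$ps, dat$grid)
  des <- buildDesign(dat$ps, bufs)
  expect_equal(dim(des), c(30L, 31L))
  expect_true("y" %in% names(des))
  ## covariates equal direct cell lookups for every point
  idx <- cellIndex(dat$grid, coords(dat$ps))
  for (k in sample(30, 5))
    expect_equal(des[[paste0("dp_p", k)]],
                 getLayer(bufs, paste0("dp_p", k))[cbind(idx$row, idx$col)])
})

test_that("multivariate designs stack rows with one-hot indicators", {
  grid <- tiny_grid(8, 8)
  set.seed(62)
  locA <- sampleDesign(grid, 15, seed = 1)
  locB <- sampleDesign(grid, 12, seed = 2)
  psA <- PointSet(locA, rnorm(15), typeLabel = "Cu")
  psB <- PointSet(locB, rnorm(12), typeLabel = "Pb",
                  methodLabel = "soil")
  psA@methodLabel <- rep("sediment", 15)
  bufs <- bufferDistances(suppressWarnings(
    PointSet(rbind(locA, locB), rnorm(27))), grid)
  des <- buildDesign(list(psA, psB), bufs, multivariate = TRUE)
  expect_equal(nrow(des), 27L)
  ind <- des[, c("TYPE_Cu", "TYPE_Pb")]
  expect_true(all(rowSums(ind) == 1))
  expect_true(all(rowSums(des[, c("METHOD_sediment", "METHOD_soil")]) == 1))
  expect_error(buildDesign(list(psA, PointSet(locB, rnorm(12))), bufs,
                           multivariate = TRUE), "typeLabel")
})

test_that("rows with missing covariates are dropped with a count", {
  grid <- tiny_grid(5, 5)
  stack <- CovariateStack(grid, list(v = matrix(1:25, 5, 5)))
  ps <- PointSet(rbind(c(1, 1), c(99, 99), c(3, 3)), 1:3)
  expect_warning(des <- buildDesign(ps, stack), "dropped|missing")
  expect_equal(nrow(des), 2L)
  expect_equal(attr(des, "nDropped"), 1L)
})

test_that("a single unpruned tree memorizes distinct-x training data", {
  set.seed(63)
  des <- data.frame(x1 = runif(30), x2 = runif(30))
  des$y <- rnorm(30)
  m <- fitForest(des, forestParams(numTrees = 1, sampleFraction = 1,
                                   replace = FALSE, minNodeSize = 1,
                                   mtry = 2, seed = 1))
  expect_equal(predictMean(m, des[, 1:2]), des$y, tolerance = 1e-12)
})

test_that("forest fits are deterministic for a fixed seed", {
  dat <- grf_points(n = 50, seed = 64)
  des <- buildDesign(dat$ps, bufferDistances(dat$ps, dat$grid))
  m1 <- fitForest(des, forestParams(numTrees = 50, seed = 7))
  m2 <- fitForest(des, forestParams(numTrees = 50, seed = 7))
  expect_identical(m1@oobMse, m2@oobMse)
  X0 <- stack_rows(bufferDistances(dat$ps, dat$grid))[1:20, ]
  expect_identical(predictMean(m1, X0), predictMean(m2, X0))
})

test_that("pure-noise targets give no out-of-bag skill", {
  set.seed(65)
  X <- as.data.frame(matrix(rnorm(200 * 5), 200, 5))
  r2s <- sapply(1:10, function(s) {
    des <- cbind(X, y = rnorm(200))
    fitForest(des, forestParams(numTrees = 100, seed = s))@oobR2
  })
  expect_true(all(r2s <= 0.1))
})

test_that("invalid forest parameters fail before fitting", {
  expect_error(forestParams(numTrees = 0), "numTrees")
  expect_error(forestParams(sampleFraction = 0), "sampleFraction")
  expect_error(forestParams(caseWeights = c(0, 0)), "caseWeights")
  des <- data.frame(x = 1:10, y = rep(1, 10))
  expect_error(fitForest(des, forestParams()), "distinct")
})

test_that("QRF weights are a normalized ensemble average", {
  dat <- grf_points(n = 40, seed = 66)
  bufs <- bufferDistances(dat$ps, dat$grid)
  m <- fitForest(buildDesign(dat$ps, bufs), forestParams(numTrees = 30,
                                                         seed = 2))
  X0 <- stack_rows(bufs)[sample(400, 25), ]
  qp <- predictQuantiles(m, X0, c(0.1, 0.5, 0.9), exposeWeights = TRUE)
  expect_true(all(abs(rowSums(qp@weights) - 1) < 1e-10))
  expect_true(all(qp@weights >= 0))
  ## Eq-16 mean equals the ranger ensemble mean
  expect_equal(qp@mean, predictMean(m, X0), tolerance = 1e-10)
})

test_that("quantiles equal a hand-built weighted ECDF inversion", {
  ## tiny forest: recompute the weights from the stored bookkeeping
  set.seed(67)
  des <- data.frame(x = runif(12), y = rnorm(12))
  m <- fitForest(des, forestParams(numTrees = 3, minNodeSize = 4, seed = 5))
  X0 <- data.frame(x = runif(4))
  qp <- predictQuantiles(m, X0, c(0.25, 0.5, 0.75), exposeWeights = TRUE)
  predNodes <- predict(m@forest, X0, type = "terminalNodes",
                       num.threads = 1)$predictions
  y <- des$y
  for (row in 1:4) {
    w <- numeric(12)
    for (b in 1:3) {
      leaf <- predNodes[row, b]
      inLeaf <- which(m@trainNodes[, b] == leaf & m@inbag[, b] > 0)
      cnt <- m@inbag[inLeaf, b]
      w[inLeaf] <- w[inLeaf] + cnt / sum(cnt) / 3
    }
    expect_equal(qp@weights[row, ], w, tolerance = 1e-12)
    for (q in c(0.25, 0.5, 0.75)) {
      ord <- order(y)
      Fhat <- cumsum(w[ord])
      expect_equal(qp@values[row, paste0("q", q)],
                   y[ord][which(Fhat >= q - 1e-12)[1]],
                   ignore_attr = TRUE)
    }
  }
})

test_that("the lower-step inversion rule picks the smallest qualifying y", {
  expect_equal(GeoForest:::weighted_quantile(c(1, 3), c(0.5, 0.5), 0.5), 1)
  expect_equal(GeoForest:::weighted_quantile(c(1, 3), c(0.5, 0.5), 0.51), 3)
  expect_equal(GeoForest:::weighted_quantile(c(5, 2, 9), c(0.2, 0.5, 0.3),
                                             c(0.2, 0.7, 0.95)), c(2, 5, 9))
})

test_that("quantiles are monotone and inside the training range", {
  dat <- grf_points(n = 60, seed = 68)
  bufs <- bufferDistances(dat$ps, dat$grid)
  m <- fitForest(buildDesign(dat$ps, bufs), forestParams(numTrees = 80,
                                                         seed = 3))
  X0 <- stack_rows(bufs)
  qp <- predictQuantiles(m, X0, c(0.05, 0.25, 0.5, 0.75, 0.95))
  expect_true(all(apply(qp@values, 1, function(r) !is.unsorted(r))))
  y <- as.numeric(targetValues(dat$ps))
  expect_true(all(qp@values >= min(y) & qp@values <= max(y)))
  expect_true(all(qp@mean >= min(y) & qp@mean <= max(y)))
  expect_true(all(qp@sigma >= 0))
})

test_that("sigma from the 68.27% interval behaves like an SD", {
  expect_equal(sigmaFromInterval(10, 6), 2)
  expect_equal(sigmaFromInterval(3, 3), 0)
  expect_error(sigmaFromInterval(1, 2), "q841")
  ## on one big Gaussian node the QRF sigma approaches the sample SD
  set.seed(69)
  des <- data.frame(x = rep(1, 2000), y = rnorm(2000, sd = 2))
  m <- fitForest(des, forestParams(numTrees = 20, seed = 4))
  qp <- predictQuantiles(m, data.frame(x = 1), c(0.5))
  expect_equal(qp@sigma, 2, tolerance = 0.2)
  expect_equal(sigmaFromDistribution(m, data.frame(x = 1)), 2,
               tolerance = 0.2)
})

test_that("probability forests emit normalized class probabilities", {
  dat <- makeCategorical(tiny_grid(15, 15), K = 3, seed = 70, n = 90)
  bufs <- classBufferDistances(dat$points, tiny_grid(15, 15))
  des <- buildDesign(dat$points, bufs)
  m <- fitForest(des, forestParams(numTrees = 100, seed = 5,
                                   task = "probability"))
  X0 <- stack_rows(bufs)
  P <- predictProbabilities(m, X0)
  expect_equal(ncol(P), 3L)
  expect_true(all(abs(rowSums(P) - 1) < 1e-10))
  expect_true(all(P >= 0))
  ## regression model refuses probability prediction
  mr <- fitForest(data.frame(x = rnorm(20), y = rnorm(20)),
                  forestParams(numTrees = 10, seed = 1))
  expect_error(predictProbabilities(mr, data.frame(x = 1)), "mode|probability")
})

test_that("binary probabilities agree with regression on the indicator", {
  grid <- tiny_grid(15, 15)
  dat <- makeCategorical(grid, K = 2, seed = 71, n = 120)
  bufs <- classBufferDistances(dat$points, grid)
  desP <- buildDesign(dat$points, bufs)
  mP <- fitForest(desP, forestParams(numTrees = 300, seed = 6,
                                     task = "probability"))
  ind <- PointSet(coords(dat$points),
                  as.numeric(targetValues(dat$points) == dat$levels[1]))
  desR <- buildDesign(ind, bufs)
  mR <- fitForest(desR, forestParams(numTrees = 300, seed = 6))
  X0 <- stack_rows(bufs)
  pP <- predictProbabilities(mP, X0)[, dat$levels[1]]
  pR <- predictMean(mR, X0)
  expect_lt(mean(abs(pP - pR)), 0.05)
})

test_that("weight-zero observations never enter the forest", {
  set.seed(72)
  n <- 40
  des <- data.frame(x1 = runif(n), x2 = runif(n))
  des$y <- des$x1 + rnorm(n, sd = 0.1)
  w <- rep(1, n); w[c(3, 17, 29)] <- 0
  m <- fitForest(des, forestParams(numTrees = 60, seed = 8, caseWeights = w))
  expect_true(all(m@inbag[c(3, 17, 29), ] == 0))
  ## predictions are invariant to those targets
  des2 <- des
  des2$y[c(3, 17, 29)] <- 1e6
  m2 <- fitForest(des2, forestParams(numTrees = 60, seed = 8,
                                     caseWeights = w))
  X0 <- data.frame(x1 = runif(10), x2 = runif(10))
  expect_identical(predictMean(m, X0), predictMean(m2, X0))
  qp1 <- predictQuantiles(m, X0, 0.5)
  qp2 <- predictQuantiles(m2, X0, 0.5)
  expect_identical(qp1@values, qp2@values)
})

test_that("multivariate prediction switches cleanly between types", {
  grid <- tiny_grid(12, 12)
  set.seed(73)
  loc <- sampleDesign(grid, 50, seed = 1)
  base <- rnorm(50)
  psA <- PointSet(loc, rep(3, 50), typeLabel = "A")     # constant variable
  psB <- PointSet(loc, base, typeLabel = "B")
  bufs <- bufferDistances(PointSet(loc, base), grid)
  des <- buildDesign(list(psA, psB), bufs, multivariate = TRUE)
  ## keep mtry high so the type indicator is always available to split on
  ## (the standard recommendation when a couple of covariates dominate)
  m <- fitForest(des, forestParams(numTrees = 300, seed = 9,
                                   mtry = ncol(des) - 1L))
  sA <- predictMultivariate(m, bufs, "A")
  ## constant type is recovered within 5% everywhere
  expect_true(all(abs(getLayer(sA, 1) - 3) <= 0.05 * 3))
  sB <- predictMultivariate(m, bufs, "B")
  expect_false(isTRUE(all.equal(getLayer(sA, 1), getLayer(sB, 1))))
  ## idempotence
  expect_equal(getLayer(predictMultivariate(m, bufs, "A"), 1),
               getLayer(sA, 1))
  expect_error(predictMultivariate(m, bufs, "Zn"), "known types")
  ## design-matrix oracle: indicator rows built by hand
  X0 <- stack_rows(bufs)
  X0$TYPE_A <- 1; X0$TYPE_B <- 0
  expect_equal(as.vector(t(getLayer(sA, 1))), predictMean(m, X0),
               tolerance = 1e-12)
})

test_that("OOB error approximates k-fold CV error", {
  dat <- grf_points(n = 300, grid = tiny_grid(25, 25),
                    vgm = exp_vgm(nugget = 0.3, psill = 1, range = 6),
                    seed = 74)
  bufs <- bufferDistances(dat$ps, dat$grid)
  des <- buildDesign(dat$ps, bufs)
  m <- fitForest(des, forestParams(numTrees = 200, seed = 10))
  rep <- crossValidate(dat$ps, "rfsp", grid = dat$grid, k = 5, seed = 11,
                       control = list(forest = forestParams(numTrees = 200)))
  cvMse <- rep@metrics$rmse^2
  expect_lt(abs(m@oobMse - cvMse) / cvMse, 0.3)
})
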