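## Scenario configuration and end-to-end pipeline execution:
## simulate (or load) -> covariates -> fit -> predict -> cross-validate
## -> compare.

config_schema <- list(
  seed = NULL, out = NULL,
  data = list(
    synthetic = list(
      grid = list(nrows = NULL, ncols = NULL, cellSize = NULL,
                  xOrigin = NULL, yOrigin = NULL, crs = NULL),
      vgm = list(family = NULL, nugget = NULL, psill = NULL, range = NULL),
      n = NULL, design = NULL, noiseSd = NULL, sourceFractions = NULL,
      transform = NULL),
    pointsFile = NULL, gridFile = NULL,
    schema = list(x = NULL, y = NULL, value = NULL, date = NULL, sd = NULL,
                  class = NULL, type = NULL, method = NULL)),
  covariates = list(buffers = NULL, coordinates = NULL,
                    pca = list(nComponents = NULL)),
  methods = list(
    ok = list(family = NULL, nBins = NULL, maxDist = NULL),
    rk = list(family = NULL, eta = NULL, nBins = NULL, maxDist = NULL),
    rfsp = list(numTrees = NULL, mtry = NULL, minNodeSize = NULL,
                sampleFraction = NULL, useCaseWeights = NULL)),
  cv = list(k = NULL, levels = NULL))

validate_keys <- function(cfg, schema, path = "") {
  for (key in names(cfg)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(schema))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(schema[[key]]) && length(schema[[key]]) &&
        is.list(cfg[[key]]))
      validate_keys(cfg[[key]], schema[[key]], full)
  }
  invisible(TRUE)
}

default_config <- function() {
  list(
    seed = 1L, out = "geoforest_run",
    data = list(synthetic = list(
      grid = list(nrows = 20L, ncols = 20L, cellSize = 1, xOrigin = 0,
                  yOrigin = 20, crs = "local"),
      vgm = list(family = "exponential", nugget = 0.1, psill = 1,
                 range = 5),
      n = 60L, design = "uniform", noiseSd = 0, transform = "none")),
    covariates = list(buffers = TRUE, coordinates = FALSE),
    methods = list(ok = list(family = "exponential"),
                   rfsp = list(numTrees = 500L)),
    cv = list(k = 5L))
}

merge_config <- function(base, user) {
  for (key in names(user)) {
    if (is.list(user[[key]]) && is.list(base[[key]]))
      base[[key]] <- merge_config(base[[key]], user[[key]])
    else base[[key]] <- user[[key]]
  }
  base
}

#' Read and validate a scenario configuration
#'
#' YAML key/value scenario files; unknown keys are rejected by name, and
#' defaults are filled in so the resolved configuration is complete.
#'
#' @param config path to a YAML file, or a list.
#' @return The resolved configuration list.
#' @export
readScenarioConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_keys(config, config_schema)
  base <- default_config()
  if (!is.null(config$methods)) base$methods <- list()   # user list wins
  cfg <- merge_config(base, config)
  if (!is.null(cfg$data$pointsFile)) cfg$data$synthetic <- NULL
  cfg
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run a full scenario
#'
#' Executes the requested stages in dependency order: simulate (or load)
#' the observations, build the covariate stacks, fit each requested
#' method on the full data and write its prediction and prediction-error
#' surfaces, cross-validate each method with refitting, and write a
#' side-by-side comparison table. Every artifact lands in the output
#' directory together with the fully resolved configuration (defaults
#' filled), a machine-readable run summary (config hash, derived stage
#' seeds, per-stage timings) and the CV reports as JSON + per-point CSV.
#' A single global seed deterministically derives all stage seeds, so
#' identical resolved configurations produce identical outputs.
#'
#' @param config YAML path or configuration list
#'   (see \code{\link{readScenarioConfig}}).
#' @param out optional output directory override.
#' @return Invisibly, a list with the comparison data.frame, the CV
#'   reports and the output directory.
#' @export
runPipeline <- function(config, out = NULL) {
  cfg <- readScenarioConfig(config)
  if (!is.null(out)) cfg$out <- out
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(cfg$seed, 8L)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    log_msg("stage ", stage, " done (", round(timings[[stage]], 2), "s)")
    r
  }

  ## --- data ----------------------------------------------------------
  dat <- clock("data", {
    if (!is.null(cfg$data$pointsFile)) {
      schema <- cfg$data$schema %||% list(x = "x", y = "y", value = "value")
      ps <- readPoints(cfg$data$pointsFile, schema = schema)
      stack <- if (!is.null(cfg$data$gridFile)) readGrid(cfg$data$gridFile)
               else NULL
      grid <- if (is.null(stack)) {
        rng <- apply(ps@coords, 2, range)
        cs <- max(diff(rng[, 1]), diff(rng[, 2])) / 40
        GridSpec(40, 40, cellSize = cs,
                 origin = c(rng[1, 1], rng[2, 2]))
      } else stack@grid
      list(ps = ps, grid = grid, truth = NULL, stack = stack)
    } else {
      sc <- cfg$data$synthetic
      grid <- GridSpec(sc$grid$nrows, sc$grid$ncols,
                       cellSize = sc$grid$cellSize,
                       origin = c(sc$grid$xOrigin, sc$grid$yOrigin),
                       crsTag = sc$grid$crs %||% "local")
      vgm <- variogramModel(sc$vgm$family, nugget = sc$vgm$nugget,
                            psill = sc$vgm$psill, rangeParam = sc$vgm$range)
      field <- simulateGRF(fieldSpec(grid, vgm,
                                     transform = sc$transform %||% "none",
                                     seed = seeds[1]))
      loc <- sampleDesign(grid, sc$n, design = sc$design %||% "uniform",
                          seed = seeds[2])
      ps <- makeDataset(field, loc, noiseSd = sc$noiseSd %||% 0,
                        sourceFractions = sc$sourceFractions,
                        seed = seeds[3])
      writePoints(ps, file.path(cfg$out, "points.csv"))
      writeGrid(field, file.path(cfg$out, "truth"))
      list(ps = ps, grid = grid, truth = field, stack = NULL)
    }
  })

  ## --- covariates ----------------------------------------------------
  stacks <- clock("covariates", {
    st <- list()
    if (!is.null(dat$stack)) st <- c(st, list(dat$stack))
    if (isTRUE(cfg$covariates$coordinates))
      st <- c(st, list(coordinateGrids(dat$grid)))
    if (!is.null(cfg$covariates$pca$nComponents) && length(st)) {
      st <- list(pcaCovariates(st[[1]],
                               cfg$covariates$pca$nComponents)$stack)
    }
    st
  })

  grid <- dat$grid
  ps <- dat$ps
  centers <- cellCenters(grid)
  validCells <- seq_len(nrow(centers))

  ## --- per-method fit + predict + cv ---------------------------------
  reports <- list()
  for (mth in names(cfg$methods)) {
    mcfg <- cfg$methods[[mth]] %||% list()
    control <- switch(mth,
      ok = list(family = mcfg$family %||% "exponential", nBins = mcfg$nBins,
                maxDist = mcfg$maxDist),
      rk = list(family = mcfg$family %||% "exponential", eta = mcfg$eta,
                nBins = mcfg$nBins, maxDist = mcfg$maxDist),
      rfsp = list(forest = forestParams(
                    numTrees = mcfg$numTrees %||% 500L,
                    mtry = mcfg$mtry %||% NA,
                    minNodeSize = mcfg$minNodeSize %||% NA,
                    sampleFraction = mcfg$sampleFraction %||% 1),
                  useCaseWeights = mcfg$useCaseWeights %||% FALSE),
      stop("unknown method: ", mth))
    clock(paste0("predict_", mth), {
      surf <- switch(mth,
        ok = {
          emp <- empiricalVariogram(ps, nBins = control$nBins %||% 15L)
          vg <- fitVariogram(emp, control$family)
          writeVariogram(vg, file.path(cfg$out, "variogram_ok.json"))
          kr <- okPredict(ps, centers, vg)
          list(pred = kr@predictions, sigma = sqrt(kr@variances))
        },
        rk = {
          if (!length(stacks)) stop("rk needs covariate layers ",
                                    "(enable covariates.coordinates ",
                                    "or supply a gridFile)")
          kr <- rkPredict(ps, stacks[[1]], targets = centers,
                          family = control$family, eta = control$eta)
          list(pred = kr@predictions, sigma = sqrt(kr@variances))
        },
        rfsp = {
          bufs <- bufferDistances(ps, grid)
          allStacks <- c(list(bufs), stacks)
          design <- buildDesign(ps, allStacks)
          params <- control$forest
          params@seed <- seeds[4]
          if (isTRUE(control$useCaseWeights) &&
              !is.null(attr(design, "caseWeights")))
            params@caseWeights <- attr(design, "caseWeights")
          model <- fitForest(design, params)
          X0 <- do.call(cbind, lapply(allStacks, function(s)
            as.data.frame(lapply(s@layers, mat_to_vec))))
          qp <- predictQuantiles(model, X0, c(0.159, 0.841))
          list(pred = qp@mean, sigma = qp@sigma)
        })
      out <- CovariateStack(grid,
        list(prediction = vec_to_mat(grid, surf$pred),
             sigma = vec_to_mat(grid, surf$sigma)))
      writeGrid(out, file.path(cfg$out, paste0("surface_", mth)))
    })
    reports[[mth]] <- clock(paste0("cv_", mth), {
      rep <- crossValidate(ps, mth, stacks = stacks, grid = grid,
                           k = cfg$cv$k %||% 5L, seed = seeds[5],
                           control = c(control,
                                       list(levels = cfg$cv$levels)))
      writeCVReport(rep,
                    jsonPath = file.path(cfg$out, paste0("cv_", mth, ".json")),
                    csvPath = file.path(cfg$out,
                                        paste0("cv_", mth, "_points.csv")))
      plotCVReport(rep, file.path(cfg$out, paste0("cv_", mth, ".png")))
      rep
    })
  }

  ## --- comparison ----------------------------------------------------
  comparison <- do.call(rbind, lapply(names(reports), function(mth) {
    m <- reports[[mth]]@metrics
    data.frame(method = mth, rmse = m$rmse, me = m$me, r2 = m$r2,
               ccc = m$ccc, rho = m$rho, z_mean = m$z_mean, z_var = m$z_var,
               resid_structure = reports[[mth]]@structureFraction)
  }))
  utils::write.csv(comparison, file.path(cfg$out, "comparison.csv"),
                   row.names = FALSE)

  resolved <- file.path(cfg$out, "config_resolved.yaml")
  yaml::write_yaml(cfg, resolved)
  summary <- list(config_hash = unname(tools::md5sum(resolved)),
                  seed = cfg$seed, stage_seeds = seeds,
                  timings = timings,
                  methods = names(cfg$methods))
  jsonlite::write_json(summary, file.path(cfg$out, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("pipeline finished: ", cfg$out)
  invisible(list(comparison = comparison, reports = reports, out = cfg$out))
}
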