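## Point and grid I/O plus point-on-grid overlay.
##
## Points travel as delimited text (CSV with header); grids travel as
## ESRI ASCII rasters (one .asc per layer) indexed by a small JSON
## manifest that carries the layer names, roles, mask and CRS tag.
## Coordinates are treated as planar/projected throughout: lon/lat input
## is accepted, but distances are always computed in coordinate units.

#' Read point observations from a delimited text file
#'
#' @param path CSV file with a header row.
#' @param schema named list mapping the PointSet fields to column names;
#'   recognised fields: \code{x}, \code{y}, \code{value}, \code{date},
#'   \code{sd}, \code{class}, \code{type}, \code{method}. Either
#'   \code{value} (numeric target) or \code{class} (categorical target)
#'   must be mapped.
#' @param sep field separator.
#' @return A \linkS4class{PointSet}. Rows whose coordinates do not parse
#'   as numbers are rejected; their count is reported in a warning and
#'   in \code{attr(, "nRejected")}.
#' @export
readPoints <- function(path, schema = list(x = "x", y = "y", value = "value"),
                       sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty table: ", path)
  need <- c("x", "y")
  if (is.null(schema$value) && is.null(schema$class))
    stop("schema must map either 'value' or 'class'")
  for (f in c(need, "value", "date", "sd", "class", "type", "method")) {
    colname <- schema[[f]]
    if (!is.null(colname) && !colname %in% names(tab))
      stop("schema error: mapped column '", colname, "' (field '", f,
           "') not present in ", path)
    if (f %in% need && is.null(colname))
      stop("schema error: field '", f, "' must be mapped")
  }
  x <- suppressWarnings(as.numeric(tab[[schema$x]]))
  y <- suppressWarnings(as.numeric(tab[[schema$y]]))
  ok <- is.finite(x) & is.finite(y)
  nRejected <- sum(!ok)
  if (nRejected > 0)
    warning(nRejected, " row(s) with unparseable coordinates rejected",
            call. = FALSE)
  if (!any(ok)) stop("no rows with valid coordinates in ", path)
  tab <- tab[ok, , drop = FALSE]
  if (tolower(schema$x) %in% c("lon", "long", "longitude") ||
      tolower(schema$y) %in% c("lat", "latitude"))
    warning("coordinates appear to be lon/lat degrees; distances are ",
            "computed in coordinate units", call. = FALSE)
  target <- if (!is.null(schema$value)) as.numeric(tab[[schema$value]])
            else factor(tab[[schema$class]])
  grab <- function(f, coerce = identity)
    if (is.null(schema[[f]])) NULL else coerce(tab[[schema[[f]]]])
  ps <- PointSet(
    coords = cbind(x[ok], y[ok]), target = target,
    ids = if ("id" %in% names(tab)) as.character(tab$id) else NULL,
    time = grab("date", as.Date),
    measSd = grab("sd", as.numeric),
    typeLabel = grab("type", as.character),
    methodLabel = grab("method", as.character))
  attr(ps, "nRejected") <- nRejected
  ps
}

#' Write a PointSet to delimited text
#'
#' Writes a header plus one record per point at full numeric precision,
#' so that \code{readPoints(writePoints(ps))} reproduces coordinates and
#' values exactly.
#'
#' @param ps a \linkS4class{PointSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePoints <- function(ps, path) {
  df <- data.frame(id = ps@ids,
                   x = full_precision(ps@coords[, 1]),
                   y = full_precision(ps@coords[, 2]),
                   stringsAsFactors = FALSE)
  if (is.factor(ps@target)) df$class <- as.character(ps@target)
  else df$value <- full_precision(as.numeric(ps@target))
  if (!is.null(ps@time)) df$date <- format(ps@time, "%Y-%m-%d")
  if (!is.null(ps@measSd)) df$sd <- full_precision(ps@measSd)
  if (!is.null(ps@typeLabel)) df$type <- ps@typeLabel
  if (!is.null(ps@methodLabel)) df$method <- ps@methodLabel
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write points to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Default schema for files written by writePoints
#' @param categorical was the target categorical?
#' @return schema list for \code{\link{readPoints}}.
#' @export
pointSchema <- function(categorical = FALSE) {
  s <- list(x = "x", y = "y")
  if (categorical) s$class <- "class" else s$value <- "value"
  s
}

## ---------------------------------------------------------------------
## Grid I/O: ESRI ASCII layers + JSON manifest
## ---------------------------------------------------------------------

write_asc <- function(grid, values, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid@ncols),
    paste("nrows", grid@nrows),
    paste("xllcorner", full_precision(grid@origin[1])),
    paste("yllcorner", full_precision(grid@origin[2] -
                                      grid@nrows * grid@cellSize)),
    paste("cellsize", full_precision(grid@cellSize)),
    "NODATA_value NA"), con)
  out <- apply(values, 1, function(r) paste(full_precision(r), collapse = " "))
  out <- gsub(" NA\\b", " NA", out)
  writeLines(out, con)
}

read_asc <- function(path) {
  hdr <- utils::read.table(path, nrows = 6, as.is = TRUE)
  h <- stats::setNames(hdr[[2]], tolower(hdr[[1]]))
  nrows <- as.integer(h[["nrows"]]); ncols <- as.integer(h[["ncols"]])
  vals <- scan(path, skip = 6, quiet = TRUE, na.strings = c("NA", h[["nodata_value"]]))
  if (length(vals) != nrows * ncols)
    stop("ASCII grid ", path, " has ", length(vals), " values, expected ",
         nrows * ncols)
  grid <- GridSpec(nrows = nrows, ncols = ncols,
                   cellSize = as.numeric(h[["cellsize"]]),
                   origin = c(as.numeric(h[["xllcorner"]]),
                              as.numeric(h[["yllcorner"]]) +
                                nrows * as.numeric(h[["cellsize"]])))
  list(grid = grid, values = matrix(vals, nrows, ncols, byrow = TRUE))
}

#' Write a covariate stack to disk
#'
#' Writes one ESRI ASCII grid (plain text, exact round trip) per layer
#' plus a JSON manifest \code{<path>.json} with the grid geometry, CRS
#' tag, layer names and roles. Masked cells are stored as NODATA.
#'
#' @param stack a \linkS4class{CovariateStack}.
#' @param path output prefix; files \code{<path>.json} and
#'   \code{<path>_<layer>.asc} are created.
#' @return The manifest path, invisibly.
#' @export
writeGrid <- function(stack, path) {
  path <- sub("\\.json$", "", path)
  grid <- stack@grid
  safe <- gsub("[^A-Za-z0-9_.-]", "_", layerNames(stack))
  files <- paste0(basename(path), "_", safe, ".asc")
  for (k in seq_along(stack@layers)) {
    v <- stack@layers[[k]]
    v[!stack@mask] <- NA_real_
    write_asc(grid, v, file.path(dirname(path), files[k]))
  }
  manifest <- list(
    format = "GeoForest grid stack v1",
    crs = grid@crsTag,
    origin = grid@origin, cellSize = grid@cellSize,
    nrows = grid@nrows, ncols = grid@ncols,
    layers = lapply(seq_along(files), function(k)
      list(name = layerNames(stack)[k], role = unname(stack@roles[k]),
           file = files[k])))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(path, ".json"))
}

#' Read a covariate stack from disk
#'
#' Accepts either a manifest written by \code{\link{writeGrid}} (or the
#' prefix it was written under) or a single \code{.asc} file, whose
#' layer is then named after the file. NODATA cells become masked cells;
#' a cell masked in any layer is masked in the stack.
#'
#' @param path manifest path, prefix, or single .asc file.
#' @return A \linkS4class{CovariateStack}.
#' @export
readGrid <- function(path) {
  if (grepl("\\.asc$", path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    a <- read_asc(path)
    nm <- sub("\\.asc$", "", basename(path))
    mask <- !is.na(a$values)
    a$values[!mask] <- 0
    return(CovariateStack(a$grid, stats::setNames(list(a$values), nm),
                          roles = "process", mask = mask))
  }
  manifest_path <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  if (!file.exists(manifest_path)) stop("file not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  grid <- GridSpec(nrows = man$nrows, ncols = man$ncols,
                   cellSize = man$cellSize,
                   origin = unlist(man$origin), crsTag = man$crs)
  layers <- list(); roles <- character()
  mask <- matrix(TRUE, grid@nrows, grid@ncols)
  for (entry in man$layers) {
    a <- read_asc(file.path(dirname(manifest_path), entry$file))
    if (!identical(dim(a$values), c(grid@nrows, grid@ncols)))
      stop("shape mismatch across layers in ", manifest_path)
    mask <- mask & !is.na(a$values)
    nm <- if (is.null(entry$name)) paste0("band_", length(layers) + 1L)
          else entry$name
    a$values[is.na(a$values)] <- 0
    layers[[nm]] <- a$values
    roles[nm] <- if (is.null(entry$role)) "process" else entry$role
  }
  CovariateStack(grid, layers, roles = roles, mask = mask)
}

## ---------------------------------------------------------------------
## Overlay
## ---------------------------------------------------------------------

#' Overlay points on a covariate stack
#'
#' Extracts, for every point, the value of each layer in the grid cell
#' containing the point (nearest-cell semantics; covariates are never
#' interpolated). Points outside the extent, or falling on masked
#' cells, yield missing values and are counted in a warning and in
#' \code{attr(, "nMissing")}.
#'
#' @param ps a \linkS4class{PointSet} (same reference system as the
#'   grid).
#' @param stack a \linkS4class{CovariateStack}.
#' @return data.frame with one row per point and one column per layer,
#'   with attribute \code{nMissing}.
#' @export
overlayPoints <- function(ps, stack) {
  idx <- cellIndex(stack@grid, ps@coords)
  n <- npoints(ps)
  out <- as.data.frame(matrix(NA_real_, n, nLayers(stack),
                              dimnames = list(ps@ids, layerNames(stack))))
  usable <- idx$inside
  flat <- cbind(idx$row, idx$col)
  masked <- rep(FALSE, n)
  masked[usable] <- !stack@mask[flat[usable, , drop = FALSE]]
  usable <- usable & !masked
  if (!any(usable)) stop("all points fall outside the grid or on masked cells")
  for (k in seq_len(nLayers(stack)))
    out[usable, k] <- stack@layers[[k]][flat[usable, , drop = FALSE]]
  nMissing <- sum(!usable)
  if (nMissing > 0)
    warning(nMissing, " point(s) outside the grid or on masked cells; ",
            "covariates set to NA", call. = FALSE)
  attr(out, "nMissing") <- nMissing
  out
}
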