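## Internal helpers shared across modules.

## Evaluate expr with a locally seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Euclidean cross-distance matrix between rows of a (m x 2) and b (n x 2).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

## Row-major cell <-> vector conversions (row 1 = top row).
vec_to_mat <- function(grid, v) matrix(v, grid@nrows, grid@ncols, byrow = TRUE)
mat_to_vec <- function(m) as.vector(t(m))

#' Cell-center coordinates of a grid
#'
#' Returns the centers of all cells in row-major order (row 1 is the
#' top/north row, columns run west to east).
#'
#' @param x a \linkS4class{GridSpec} or \linkS4class{CovariateStack}.
#' @return A two-column matrix with \code{nrows * ncols} rows.
#' @export
setMethod("cellCenters", "GridSpec", function(x) {
  xs <- x@origin[1] + (seq_len(x@ncols) - 0.5) * x@cellSize
  ys <- x@origin[2] - (seq_len(x@nrows) - 0.5) * x@cellSize
  cbind(x = rep(xs, times = x@nrows), y = rep(ys, each = x@ncols))
})

#' @rdname cellCenters-GridSpec-method
setMethod("cellCenters", "CovariateStack", function(x) cellCenters(x@grid))

#' Locate points on a grid
#'
#' Maps planar coordinates to (row, col) cell indices using half-open
#' cell intervals, so that every in-extent point belongs to exactly one
#' cell: column \code{j} covers \code{[x_left + (j-1)c, x_left + j c)}
#' and row \code{i} covers \code{(y_top - i c, y_top - (i-1) c]}.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param xy two-column coordinate matrix.
#' @return data.frame with columns \code{row}, \code{col} (NA outside
#'   the extent) and \code{inside}.
#' @export
cellIndex <- function(grid, xy) {
  xy <- as.matrix(xy)
  col <- floor((xy[, 1] - grid@origin[1]) / grid@cellSize) + 1
  row <- floor((grid@origin[2] - xy[, 2]) / grid@cellSize) + 1
  ## top edge belongs to row 1
  row[grid@origin[2] - xy[, 2] == 0] <- 1
  inside <- col >= 1 & col <= grid@ncols & row >= 1 & row <= grid@nrows
  col[!inside] <- NA_integer_
  row[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

## Format numbers at full double precision for text serialization.
full_precision <- function(x) formatC(x, digits = 17, format = "g")

## Stable stage-seed derivation from one global seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
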