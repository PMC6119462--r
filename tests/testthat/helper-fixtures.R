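## Shared fixtures: everything is generated in code at test time.

tiny_grid <- function(nr = 10, nc = 10, cs = 1) GridSpec(nr, nc, cellSize = cs)

exp_vgm <- function(nugget = 0.1, psill = 1, range = 5)
  variogramModel("exponential", nugget = nugget, psill = psill,
                 rangeParam = range)

## A small sampled GRF data set (points at distinct cell centers).
grf_points <- function(n = 60, grid = tiny_grid(20, 20), vgm = exp_vgm(),
                       seed = 1, noiseSd = 0) {
  field <- simulateGRF(fieldSpec(grid, vgm, seed = seed))
  loc <- sampleDesign(grid, n, seed = seed + 1)
  ps <- makeDataset(field, loc, noiseSd = noiseSd, seed = seed + 2)
  list(ps = ps, field = field, grid = grid, cells = attr(loc, "cells"))
}

## Flatten all layers of a stack into a prediction data.frame (row-major
## cell order).
stack_rows <- function(stack)
  as.data.frame(lapply(stack@layers, function(l) as.vector(t(l))))

layer_vec <- function(stack, name = 1) as.vector(t(stack@layers[[name]]))

r2_of <- function(y, p) 1 - sum((p - y)^2) / sum((y - mean(y))^2)
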