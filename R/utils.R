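# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic operations in the package
# funnel through this so that a seed argument fully determines the result.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-stage seed derivation from one base seed (kept < 2^31)
stage_seed <- function(base_seed, stage) {
  offsets <- c(landscape = 1, roads = 2, covariates = 3, individuals = 4,
               telemetry = 5, error = 6, ranges = 7, design = 8, ratio = 9,
               forest = 10, interpret = 11, validate = 12)
  k <- if (is.character(stage)) unname(offsets[stage]) else as.numeric(stage)
  if (is.na(k)) stop("unknown pipeline stage: ", stage)
  as.integer((as.numeric(base_seed) * 7919 + k * 104729) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# grid geometry: origin = lower-left corner of the map; the center of
# 0-based cell (row r, col c) is origin + (c + 0.5, r + 0.5) * cell_size.
# R matrices store grid row r in matrix row r + 1 (matrix row 1 = bottom).
grid_geometry <- function(n_rows, n_cols, cell_size, origin = c(0, 0)) {
  list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
       cell_size = cell_size, origin = as.numeric(origin))
}

grid_extent <- function(geom) {
  c(xmin = geom$origin[1], xmax = geom$origin[1] + geom$n_cols * geom$cell_size,
    ymin = geom$origin[2], ymax = geom$origin[2] + geom$n_rows * geom$cell_size)
}

cell_centers_x <- function(geom) geom$origin[1] + (seq_len(geom$n_cols) - 0.5) * geom$cell_size
cell_centers_y <- function(geom) geom$origin[2] + (seq_len(geom$n_rows) - 0.5) * geom$cell_size

# map x/y to matrix indices (1-based), clamping points on the extent edge
# into the edge cell; out-of-extent points are an error naming the offender
point_to_cell <- function(geom, x, y) {
  ext <- grid_extent(geom)
  bad <- which(x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"])
  if (length(bad))
    stop("point outside raster extent at index ", bad[1],
         " (x = ", x[bad[1]], ", y = ", y[bad[1]], ")")
  col <- pmin(pmax(floor((x - geom$origin[1]) / geom$cell_size) + 1, 1), geom$n_cols)
  row <- pmin(pmax(floor((y - geom$origin[2]) / geom$cell_size) + 1, 1), geom$n_rows)
  cbind(row = row, col = col)
}

habitat_classes <- function() c("forest", "agriculture", "grassland", "water", "developed")
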