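# plain-text raster and vector exchange formats
#
# Rasters are written as ESRI ASCII grids (.asc): a 6-line header followed by
# rows of values top-down. Class maps carry a JSON legend sidecar mapping the
# integer codes 1..5 to habitat class names. Roads and polygons travel as
# GeoJSON. All formats are plain text so artifacts are diffable and portable.

write_ascii_grid <- function(values, geom, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", geom$n_cols),
    paste("nrows", geom$n_rows),
    paste("xllcorner", format(geom$origin[1], scientific = FALSE)),
    paste("yllcorner", format(geom$origin[2], scientific = FALSE)),
    paste("cellsize", format(geom$cell_size, scientific = FALSE)),
    "NODATA_value -9999"), con)
  # matrix row 1 = bottom grid row; .asc rows run top-down
  for (i in rev(seq_len(geom$n_rows)))
    writeLines(paste(formatC(values[i, ], digits = digits, format = "g"),
                     collapse = " "), con)
  invisible(path)
}

read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  nc <- as.integer(h[["ncols"]]); nr <- as.integer(h[["nrows"]])
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE] # back to bottom-up storage
  list(values = m,
       geom = grid_geometry(nr, nc, h[["cellsize"]],
                            c(h[["xllcorner"]], h[["yllcorner"]])))
}

#' Write / read a habitat class map
#'
#' The map is stored as an ESRI ASCII grid of integer codes plus a JSON
#' legend sidecar (`<path>.legend.json`) naming the classes.
#'
#' @param map a `habitat_map`
#' @param path file path for the `.asc` grid
#' @return `write_habitat_map` returns `path` invisibly; `read_habitat_map`
#'   returns a `habitat_map`.
#' @export
write_habitat_map <- function(map, path) {
  write_ascii_grid(map$classes, map$geom, path, digits = 1)
  jsonlite::write_json(as.list(stats::setNames(seq_along(map$levels), map$levels)),
                       paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_habitat_map
#' @export
read_habitat_map <- function(path) {
  g <- read_ascii_grid(path)
  legend <- jsonlite::read_json(paste0(path, ".legend.json"))
  levels <- names(sort(unlist(legend)))
  new_habitat_map(matrix(as.integer(g$values), nrow(g$values)), g$geom, levels)
}

#' Write / read a road network as GeoJSON
#'
#' LineString features with a `road_class` property (`major` or `minor`).
#'
#' @param roads a `road_network`
#' @param path output `.geojson` path
#' @export
write_roads_geojson <- function(roads, path) {
  feats <- lapply(roads$roads, function(rd) {
    list(type = "Feature",
         properties = list(road_class = rd$class),
         geometry = list(type = "LineString",
                         coordinates = apply(rd$coords, 1, as.numeric,
                                             simplify = FALSE)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_roads_geojson
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  roads <- lapply(gj$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(p) as.numeric(unlist(p))))
    list(coords = coords, class = f$properties$road_class)
  })
  structure(list(roads = roads), class = "road_network")
}

# polygons: list of rings (each an n x 2 matrix, outer rings CCW) grouped
# into parts: list(list(outer = ring, holes = list(...)), ...)
write_polygons_geojson <- function(parts, path, properties = NULL) {
  close_ring <- function(r) {
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
    apply(r, 1, as.numeric, simplify = FALSE)
  }
  coords <- lapply(parts, function(p)
    c(list(close_ring(p$outer)), lapply(p$holes, close_ring)))
  geom <- if (length(coords) == 1)
    list(type = "Polygon", coordinates = coords[[1]])
  else list(type = "MultiPolygon", coordinates = coords)
  feat <- list(type = "Feature", properties = properties %||% list(),
               geometry = geom)
  jsonlite::write_json(list(type = "FeatureCollection", features = list(feat)),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
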