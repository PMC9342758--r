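# ranges: study-area delineation (buffer--dissolve) and 95% kernel home
# ranges with a direct plug-in bandwidth.
#
# The study area is the union of equal-radius discs about the telemetry
# points. Its area is computed exactly by Green's theorem over the exposed
# boundary arcs (each disc's boundary minus the angular intervals covered by
# overlapping discs), so no polygon-clipping library is needed; rings are
# discretized only for export.

#' Radius of the circle with a given area
#'
#' @param area area in square meters (>= 0)
#' @return radius in meters, `sqrt(area / pi)`. 135.0 km^2 gives 6555 m
#'   (nearest integer), the buffer radius used throughout the defaults.
#' @export
radius_from_area <- function(area) {
  if (area < 0) stop("area must be nonnegative")
  sqrt(area / pi)
}

#' Area in hectares of a circle with a given radius
#'
#' @param radius radius in meters (>= 0)
#' @return area in hectares, `pi * radius^2 / 1e4`; a 94 m radius gives 2.8 ha
#' @export
circle_area_ha <- function(radius) {
  stopifnot(radius >= 0)
  pi * radius^2 / 1e4
}

# merge angular intervals (rows lo, hi; may wrap) on a circle; returns the
# exposed complement as a matrix of non-wrapping [lo, hi] intervals in
# [0, 2pi], or NULL when fully covered
exposed_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0)
    return(matrix(c(0, 2 * pi), ncol = 2))
  # normalize and split wrapping intervals
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(iv))) {
    lo <- iv[i, 1] %% (2 * pi); hi <- iv[i, 2] %% (2 * pi)
    if (iv[i, 2] - iv[i, 1] >= 2 * pi) return(NULL)
    if (lo <= hi) out <- rbind(out, c(lo, hi))
    else out <- rbind(out, c(lo, 2 * pi), c(0, hi))
  }
  out <- out[order(out[, 1]), , drop = FALSE]
  merged <- out[1, , drop = FALSE]
  for (i in seq_len(nrow(out))[-1]) {
    j <- nrow(merged)
    if (out[i, 1] <= merged[j, 2]) merged[j, 2] <- max(merged[j, 2], out[i, 2])
    else merged <- rbind(merged, out[i, ])
  }
  # complement within [0, 2pi]
  comp <- matrix(numeric(0), ncol = 2)
  cur <- 0
  for (i in seq_len(nrow(merged))) {
    if (merged[i, 1] > cur) comp <- rbind(comp, c(cur, merged[i, 1]))
    cur <- max(cur, merged[i, 2])
  }
  if (cur < 2 * pi) comp <- rbind(comp, c(cur, 2 * pi))
  if (nrow(comp) == 0) NULL else comp
}

#' Delineate the study area by buffer and dissolve
#'
#' Buffers every point by `buffer_radius` and dissolves overlapping discs.
#' Area and boundary are exact (circular-arc geometry); exported rings are
#' discretized with at least 256 vertices per full circle.
#'
#' @param points matrix or data.frame with columns x, y (>= 1 point)
#' @param buffer_radius disc radius in meters (> 0); conventionally the mean
#'   home-range radius
#' @return a `study_area` region with exact `area`, polygon `rings`, and
#'   `n_polygons` (connected components)
#' @export
study_area <- function(points, buffer_radius) {
  pts <- unique(as.matrix(as.data.frame(points)[, c("x", "y")]))
  if (nrow(pts) < 1) stop("at least one point required")
  stopifnot(buffer_radius > 0)
  n <- nrow(pts); r <- buffer_radius
  covered <- vector("list", n)  # angular intervals covered on each circle
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  fully <- rep(FALSE, n)
  acc <- lapply(seq_len(n), function(i) list())
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      dx <- pts[js, 1] - pts[i, 1]; dy <- pts[js, 2] - pts[i, 2]
      d <- sqrt(dx^2 + dy^2)
      near <- which(d < 2 * r)
      for (k in near) {
        j <- js[k]
        pi_ <- find(i); pj <- find(j)
        if (pi_ != pj) parent[pj] <- pi_
        b <- acos(d[k] / (2 * r))
        a_ij <- atan2(dy[k], dx[k])
        acc[[i]][[length(acc[[i]]) + 1L]] <- c(a_ij - b, a_ij + b)
        acc[[j]][[length(acc[[j]]) + 1L]] <- c(a_ij + pi - b, a_ij + pi + b)
      }
    }
  }
  for (i in seq_len(n))
    if (length(acc[[i]])) covered[[i]] <- do.call(rbind, acc[[i]])
  comp <- vapply(seq_len(n), find, integer(1))

  area <- 0
  arcs <- list()  # per exposed arc: circle index, theta1, theta2
  for (i in seq_len(n)) {
    exp_iv <- exposed_intervals(covered[[i]])
    if (is.null(exp_iv)) { fully[i] <- TRUE; next }
    for (k in seq_len(nrow(exp_iv))) {
      t1 <- exp_iv[k, 1]; t2 <- exp_iv[k, 2]
      # Green's theorem contribution of a CCW arc of circle i
      area <- area + 0.5 * (r^2 * (t2 - t1) +
        pts[i, 1] * r * (sin(t2) - sin(t1)) +
        pts[i, 2] * r * (cos(t1) - cos(t2)))
      arcs[[length(arcs) + 1]] <- list(circle = i, t1 = t1, t2 = t2)
    }
  }
  rings <- assemble_rings(arcs, pts, r)
  area <- unname(area)
  structure(list(centers = pts, radius = r, area = area, rings = rings,
                 n_polygons = length(unique(comp[!fully])),
                 components = comp),
            class = c("study_area", "sa_region"))
}

# chain exposed arcs into closed rings; arcs ordered CCW on their own circle,
# endpoints matched by rounded coordinates
assemble_rings <- function(arcs, pts, r) {
  if (!length(arcs)) return(list())
  key <- function(p) paste(round(p[1] / (r * 1e-9)), round(p[2] / (r * 1e-9)))
  pt_at <- function(a, t) pts[a$circle, ] + r * c(cos(t), sin(t))
  starts <- vapply(arcs, function(a) key(pt_at(a, a$t1)), character(1))
  used <- rep(FALSE, length(arcs))
  start_lookup <- split(seq_along(arcs), starts)
  rings <- list()
  for (s in seq_along(arcs)) {
    if (used[s]) next
    ring_pts <- NULL
    cur <- s
    repeat {
      used[cur] <- TRUE
      a <- arcs[[cur]]
      npt <- max(2, ceiling(256 * (a$t2 - a$t1) / (2 * pi)))
      th <- seq(a$t1, a$t2, length.out = npt + 1)
      seg <- cbind(pts[a$circle, 1] + r * cos(th),
                   pts[a$circle, 2] + r * sin(th))
      ring_pts <- rbind(ring_pts, seg[-nrow(seg), , drop = FALSE])
      endk <- key(pt_at(a, a$t2))
      if (abs(a$t2 - a$t1 - 2 * pi) < 1e-12) break  # full circle
      nxt <- start_lookup[[endk]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) {
        # closed back to the start of this ring
        break
      }
      cur <- nxt[1]
    }
    colnames(ring_pts) <- c("x", "y")
    rings[[length(rings) + 1]] <- ring_pts
  }
  rings
}

#' @export
print.study_area <- function(x, ...) {
  cat("study_area:", nrow(x$centers), "buffered points, radius",
      round(x$radius), "m,", x$n_polygons, "polygon(s), area",
      format(x$area / 1e6, digits = 6), "km^2\n")
  invisible(x)
}

# ---- region generics: every availability domain supports these ----

#' Region interface: area, bounding box, membership
#'
#' Availability domains (study areas, kernel home ranges, rectangles) share a
#' small interface used by the design module's rejection sampler. Boundary
#' points count as inside.
#'
#' @param region a region object
#' @param x,y point coordinates
#' @return `region_area`: square meters; `region_bbox`: named vector
#'   xmin/xmax/ymin/ymax; `region_contains`: logical vector
#' @export
region_area <- function(region) UseMethod("region_area")
#' @rdname region_area
#' @export
region_bbox <- function(region) UseMethod("region_bbox")
#' @rdname region_area
#' @export
region_contains <- function(region, x, y) UseMethod("region_contains")

#' @export
region_area.study_area <- function(region) region$area
#' @export
region_bbox.study_area <- function(region) {
  c(xmin = min(region$centers[, 1]) - region$radius,
    xmax = max(region$centers[, 1]) + region$radius,
    ymin = min(region$centers[, 2]) - region$radius,
    ymax = max(region$centers[, 2]) + region$radius)
}
#' @export
region_contains.study_area <- function(region, x, y) {
  out <- rep(FALSE, length(x))
  r2 <- region$radius^2
  for (i in seq_len(nrow(region$centers)))
    out <- out | ((x - region$centers[i, 1])^2 +
                  (y - region$centers[i, 2])^2 <= r2)
  out
}

#' Rectangular region
#'
#' Convenience availability domain covering a rectangle (e.g. a full map
#' extent via `as_region(map)`).
#' @param xmin,xmax,ymin,ymax rectangle bounds
#' @export
rect_region <- function(xmin, xmax, ymin, ymax) {
  xmin <- unname(xmin); xmax <- unname(xmax)
  ymin <- unname(ymin); ymax <- unname(ymax)
  stopifnot(xmax > xmin, ymax > ymin)
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = c("rect_region", "sa_region"))
}

#' @rdname rect_region
#' @param map a `habitat_map`
#' @export
as_region <- function(map) {
  ext <- grid_extent(map$geom)
  rect_region(ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"])
}

#' @export
region_area.rect_region <- function(region)
  (region$xmax - region$xmin) * (region$ymax - region$ymin)
#' @export
region_bbox.rect_region <- function(region)
  c(xmin = region$xmin, xmax = region$xmax,
    ymin = region$ymin, ymax = region$ymax)
#' @export
region_contains.rect_region <- function(region, x, y)
  x >= region$xmin & x <= region$xmax & y >= region$ymin & y <= region$ymax

# ---- direct plug-in bandwidth ----

# univariate two-stage direct plug-in bandwidth (Gaussian kernel):
# normal-reference start for psi_8, two refinement stages (psi_6, psi_4),
# then h = (R(K) / (mu2^2 psi_4 n))^(1/5).
dpi_bandwidth_1d <- function(x) {
  n <- length(x)
  sigma <- min(stats::sd(x), stats::IQR(x) / 1.349)
  if (!is.finite(sigma) || sigma <= 0) sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma <= 0)
    stop("singular data: zero scale in a coordinate")
  psi8 <- 105 / (32 * sqrt(pi) * sigma^9)
  g1 <- (30 / (sqrt(2 * pi) * psi8 * n))^(1 / 9)
  psi6 <- cpp_psi(x, g1, 6L)
  if (!is.finite(psi6) || psi6 >= 0) {
    warning("plug-in stage failed; falling back to normal-scale bandwidth")
    return((4 / (3 * n))^(1 / 5) * sigma)
  }
  g2 <- (-6 / (sqrt(2 * pi) * psi6 * n))^(1 / 7)
  psi4 <- cpp_psi(x, g2, 4L)
  if (!is.finite(psi4) || psi4 <= 0) {
    warning("plug-in stage failed; falling back to normal-scale bandwidth")
    return((4 / (3 * n))^(1 / 5) * sigma)
  }
  (1 / (2 * sqrt(pi) * psi4 * n))^(1 / 5)
}

#' Direct plug-in bandwidth matrix
#'
#' Two-stage direct plug-in selector (Wand-Jones family) applied per
#' coordinate: density functionals psi_6 and psi_4 are estimated with a
#' normal-reference start and two refinement stages, giving a diagonal
#' bandwidth matrix `diag(h1^2, h2^2)` in m^2. Falls back to the
#' normal-scale bandwidth with a warning if a stage degenerates.
#'
#' @param points matrix or data.frame with columns x, y; >= 10 non-collinear
#'   points
#' @return 2x2 symmetric positive-definite bandwidth matrix
#' @export
plugin_bandwidth <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  if (nrow(pts) < 10) stop("at least 10 points required")
  if (stats::sd(pts[, 1]) == 0 || stats::sd(pts[, 2]) == 0 ||
      abs(stats::cor(pts[, 1], pts[, 2])) > 1 - 1e-12)
    stop("singular data: points are collinear or degenerate")
  H <- diag(c(dpi_bandwidth_1d(pts[, 1])^2, dpi_bandwidth_1d(pts[, 2])^2))
  dimnames(H) <- list(c("x", "y"), c("x", "y"))
  H
}

#' Kernel home range
#'
#' Gaussian-kernel KDE with the direct plug-in bandwidth, evaluated on an
#' `n_grid` x `n_grid` lattice spanning the points plus 3 bandwidth standard
#' deviations per axis. The `iso_level` superlevel set is found by ranking
#' grid densities and accumulating mass (Riemann sum) until the target level
#' is enclosed; that set is polygonized via contour lines.
#'
#' @param points matrix or data.frame with columns x, y
#' @param iso_level probability mass of the home range (default 0.95)
#' @param n_grid evaluation grid resolution per axis (>= 50, default 200)
#' @param id optional individual id carried on the result
#' @return a `home_range` region: rings, bandwidth, enclosed `mass`, `area`
#' @export
kde_home_range <- function(points, iso_level = 0.95, n_grid = 200, id = NULL) {
  stopifnot(iso_level > 0, iso_level < 1, n_grid >= 50)
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  H <- plugin_bandwidth(pts)
  h <- sqrt(diag(H))
  gx <- seq(min(pts[, 1]) - 3 * h[1], max(pts[, 1]) + 3 * h[1],
            length.out = n_grid)
  gy <- seq(min(pts[, 2]) - 3 * h[2], max(pts[, 2]) + 3 * h[2],
            length.out = n_grid)
  # separable Gaussian product kernel: dens[i, j] = f(gx[i], gy[j])
  Ax <- outer(gx, pts[, 1], function(g, p) stats::dnorm(g - p, sd = h[1]))
  Ay <- outer(gy, pts[, 2], function(g, p) stats::dnorm(g - p, sd = h[2]))
  dens <- (Ax %*% t(Ay)) / nrow(pts)
  total <- sum(dens)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord])
  threshold <- dens[ord][which(cum >= iso_level * total)[1]]
  mask <- dens >= threshold
  mass <- sum(dens[mask]) / total
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  rings <- lapply(grDevices::contourLines(gx, gy, dens, levels = threshold),
                  function(cl) cbind(x = cl$x, y = cl$y))
  n_poly <- length(unique(as.vector(
    cpp_label_components(matrix(as.integer(mask), n_grid))[mask])))
  structure(list(individual_id = id, rings = rings, iso_level = iso_level,
                 bandwidth = H, gx = gx, gy = gy, threshold = threshold,
                 mask = mask, mass = mass, area = sum(mask) * cell,
                 n_polygons = n_poly),
            class = c("home_range", "sa_region"))
}

#' @export
print.home_range <- function(x, ...) {
  cat("home_range", if (!is.null(x$individual_id)) x$individual_id else "",
      ": ", round(100 * x$iso_level), "% isopleth, area ",
      format(x$area / 1e6, digits = 4), " km^2, enclosed mass ",
      round(x$mass, 3), "\n", sep = "")
  invisible(x)
}

#' @export
region_area.home_range <- function(region) region$area
#' @export
region_bbox.home_range <- function(region)
  c(xmin = min(region$gx), xmax = max(region$gx),
    ymin = min(region$gy), ymax = max(region$gy))
#' @export
region_contains.home_range <- function(region, x, y) {
  dx <- region$gx[2] - region$gx[1]; dy <- region$gy[2] - region$gy[1]
  i <- round((x - region$gx[1]) / dx) + 1
  j <- round((y - region$gy[1]) / dy) + 1
  ok <- i >= 1 & i <= length(region$gx) & j >= 1 & j <= length(region$gy)
  out <- rep(FALSE, length(x))
  out[ok] <- region$mask[cbind(i[ok], j[ok])]
  out
}

#' Export a region's polygons to GeoJSON
#'
#' Rings with negative signed area are written as holes of the enclosing
#' outer ring. A JSON sidecar (`<path>.meta.json`) carries the bandwidth and
#' achieved isopleth mass for home ranges.
#'
#' @param region a `study_area` or `home_range`
#' @param path output `.geojson` path
#' @export
write_region_geojson <- function(region, path) {
  rings <- region$rings
  if (!length(rings)) {
    jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                         path, auto_unbox = TRUE)
    return(invisible(path))
  }
  signed_area <- function(rg) {
    x <- rg[, 1]; y <- rg[, 2]
    sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  }
  sa <- vapply(rings, signed_area, numeric(1))
  outers <- which(sa >= 0); holes <- which(sa < 0)
  in_ring <- function(p, rg)
    as.logical(sp_point_in_polygon(p[1], p[2], rg[, 1], rg[, 2]))
  parts <- lapply(outers, function(o) list(outer = rings[[o]], holes = list()))
  for (hh in holes) {
    p <- rings[[hh]][1, ]
    placed <- FALSE
    for (k in seq_along(outers)) {
      if (in_ring(p, rings[[outers[k]]])) {
        parts[[k]]$holes <- c(parts[[k]]$holes, list(rings[[hh]]))
        placed <- TRUE
        break
      }
    }
    if (!placed) parts <- c(parts, list(list(outer = rings[[hh]],
                                             holes = list())))
  }
  write_polygons_geojson(parts, path)
  if (inherits(region, "home_range"))
    jsonlite::write_json(list(bandwidth = region$bandwidth,
                              iso_level = region$iso_level,
                              mass = region$mass),
                         paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = 10)
  invisible(path)
}

# even-odd ray casting, boundary treated as inside-ish (adequate for hole
# assignment where points are never on the boundary)
sp_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}
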