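# landscape_sim: synthetic categorical landscapes and road networks
#
# The generator draws one Gaussian noise field per habitat class, smooths each
# with a Gaussian blur (sigma = smoothing_length / cell_size), and labels every
# cell by the argmax of weight_k + field_k. The per-class weights are then
# calibrated by iterative proportional adjustment until the realized class
# composition matches the target within tolerance. Smoothing induces spatial
# autocorrelation, so classes form contiguous interspersed patches whose
# typical size grows with smoothing_length.

#' Configuration for a synthetic landscape
#'
#' @param n_rows,n_cols grid dimensions (>= 10)
#' @param cell_size cell edge length in meters (default 30, the resolution of
#'   the land-cover product the generator emulates)
#' @param target_composition proportions of the five classes (forest,
#'   agriculture, grassland, water, developed); must sum to 1
#' @param smoothing_length patch-size control, in meters
#' @param n_major_roads,n_minor_roads number of road polylines per class
#' @param seed integer seed controlling all landscape randomness
#' @return a `landscape_config`
#' @export
landscape_config <- function(n_rows, n_cols, cell_size = 30,
                             target_composition = c(0.54, 0.35, 0.04, 0.02, 0.05),
                             smoothing_length = 300,
                             n_major_roads = 2, n_minor_roads = 4, seed = 1) {
  stopifnot(n_rows >= 10, n_cols >= 10, cell_size > 0,
            length(target_composition) == 5, all(target_composition >= 0),
            n_major_roads >= 0, n_minor_roads >= 0)
  if (abs(sum(target_composition) - 1) > 1e-9)
    stop("target_composition must sum to 1")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size,
                 target_composition = stats::setNames(target_composition,
                                                      habitat_classes()),
                 smoothing_length = smoothing_length,
                 n_major_roads = as.integer(n_major_roads),
                 n_minor_roads = as.integer(n_minor_roads),
                 seed = as.integer(seed)),
            class = "landscape_config")
}

new_habitat_map <- function(classes, geom, levels = habitat_classes()) {
  stopifnot(is.matrix(classes), nrow(classes) >= 1, ncol(classes) >= 1)
  structure(list(classes = classes, geom = geom, levels = levels),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat("habitat_map:", x$geom$n_rows, "x", x$geom$n_cols, "cells,",
      x$geom$cell_size, "m resolution\n")
  print(round(composition(x), 4))
  invisible(x)
}

# separable Gaussian blur with edge renormalization (kernel truncated at 3 sd)
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  band <- function(n) {
    h <- ceiling(3 * sigma)
    idx <- seq_len(n)
    B <- outer(idx, idx, function(i, j)
      ifelse(abs(i - j) <= h, exp(-(i - j)^2 / (2 * sigma^2)), 0))
    B / rowSums(B)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Generate a synthetic habitat class map
#'
#' Labels each cell with the argmax over classes of `weight_k + field_k`,
#' where `field_k` is a smoothed standardized Gaussian noise field and the
#' weights are calibrated iteratively so the realized composition matches
#' `config$target_composition` within 1 percentage point per class.
#'
#' @param config a [landscape_config()]
#' @return a `habitat_map`
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  target <- config$target_composition
  K <- length(target)
  active <- which(target > 0)
  geom <- grid_geometry(config$n_rows, config$n_cols, config$cell_size)
  sigma <- config$smoothing_length / config$cell_size

  fields <- with_seed(config$seed, {
    lapply(seq_len(K), function(k) {
      if (!(k %in% active)) return(NULL)
      f <- gaussian_blur(matrix(stats::rnorm(config$n_rows * config$n_cols),
                                config$n_rows, config$n_cols), sigma)
      (f - mean(f)) / stats::sd(f)
    })
  })

  if (length(active) == 1L) {
    cls <- matrix(active, config$n_rows, config$n_cols)
    return(new_habitat_map(cls, geom))
  }

  assign_labels <- function(w) {
    best <- fields[[active[1]]] + w[active[1]]
    lab <- matrix(active[1], config$n_rows, config$n_cols)
    for (k in active[-1]) {
      sc <- fields[[k]] + w[k]
      upd <- sc > best
      lab[upd] <- k
      best[upd] <- sc[upd]
    }
    lab
  }

  w <- numeric(K)
  lambda <- 1.5
  best_err <- Inf
  best_lab <- NULL
  for (iter in seq_len(200)) {
    lab <- assign_labels(w)
    realized <- tabulate(lab, K) / length(lab)
    err <- target - realized
    if (max(abs(err)) < best_err) {
      best_err <- max(abs(err))
      best_lab <- lab
    }
    if (best_err <= 0.0025) break
    w[active] <- w[active] + lambda * err[active]
  }
  if (best_err > 0.01) {
    realized <- tabulate(best_lab, K) / length(best_lab)
    worst <- which.max(abs(target - realized))
    stop("landscape composition calibration failed: class '",
         habitat_classes()[worst], "' off by ",
         round(abs(target - realized)[worst], 4),
         " after 200 iterations")
  }
  new_habitat_map(best_lab, geom)
}

#' Realized class composition of a habitat map
#'
#' @param map a `habitat_map`
#' @return named vector of 5 proportions summing to 1
#' @export
composition <- function(map) {
  stopifnot(inherits(map, "habitat_map"))
  stats::setNames(tabulate(map$classes, length(map$levels)) /
                    length(map$classes), map$levels)
}

#' Generate a synthetic road network
#'
#' Each road is a polyline crossing the full map extent (entering and leaving
#' on opposite edges) with jittered intermediate vertices, independent of the
#' habitat pattern. Deterministic under `seed`.
#'
#' @param config a [landscape_config()]
#' @param seed integer seed (defaults to `config$seed`)
#' @return a `road_network`: list of `(coords, class)` polylines
#' @export
generate_roads <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "landscape_config"),
            config$n_major_roads >= 0, config$n_minor_roads >= 0)
  ext <- grid_extent(grid_geometry(config$n_rows, config$n_cols,
                                   config$cell_size))
  one_road <- function() {
    vertical <- stats::runif(1) < 0.5
    n_mid <- 3L
    if (vertical) {
      xs <- stats::runif(2, ext["xmin"], ext["xmax"])
      x <- seq(xs[1], xs[2], length.out = n_mid + 2)
      y <- seq(ext["ymin"], ext["ymax"], length.out = n_mid + 2)
    } else {
      ys <- stats::runif(2, ext["ymin"], ext["ymax"])
      y <- seq(ys[1], ys[2], length.out = n_mid + 2)
      x <- seq(ext["xmin"], ext["xmax"], length.out = n_mid + 2)
    }
    jit <- 0.08 * min(ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"])
    mid <- 2:(n_mid + 1)
    if (vertical) x[mid] <- x[mid] + stats::rnorm(n_mid, 0, jit)
    else y[mid] <- y[mid] + stats::rnorm(n_mid, 0, jit)
    cbind(x = pmin(pmax(x, ext["xmin"]), ext["xmax"]),
          y = pmin(pmax(y, ext["ymin"]), ext["ymax"]))
  }
  roads <- with_seed(seed, {
    c(lapply(seq_len(config$n_major_roads),
             function(i) list(coords = one_road(), class = "major")),
      lapply(seq_len(config$n_minor_roads),
             function(i) list(coords = one_road(), class = "minor")))
  })
  structure(list(roads = roads), class = "road_network")
}

#' Mean patch area of a habitat map
#'
#' Patches are 4-connected components of equal class. Used to verify that
#' patch size grows with `smoothing_length`.
#'
#' @param map a `habitat_map`
#' @return mean patch area in square meters
#' @export
mean_patch_area <- function(map) {
  lab <- cpp_label_components(map$classes)
  mean(tabulate(lab)) * map$geom$cell_size^2
}
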