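# fixtures are built in code: small deterministic class maps, a reusable
# synthetic world, and independent brute-force oracles

CLASSES <- c("forest", "agriculture", "grassland", "water", "developed")

# a habitat map from an explicit integer matrix (grid row 1 = bottom)
map_from_matrix <- function(classes, cell_size = 30, origin = c(0, 0)) {
  selscape:::new_habitat_map(
    classes, selscape:::grid_geometry(nrow(classes), ncol(classes),
                                      cell_size, origin))
}

# random 5-class map with all classes present
random_map <- function(nr, nc, cell_size = 30, seed = 1) {
  set.seed(seed)
  cls <- matrix(sample(1:5, nr * nc, replace = TRUE,
                       prob = c(0.4, 0.3, 0.1, 0.1, 0.1)), nr, nc)
  cls[cbind(1:5, 1:5)] <- 1:5 # guarantee presence
  map_from_matrix(cls, cell_size)
}

# a small calibrated world shared by heavier tests
make_world <- function(seed = 1, nr = 100, nc = 100, cell_size = 30,
                       smoothing = 200, window_radius = 150) {
  cfg <- landscape_config(nr, nc, cell_size = cell_size,
                          smoothing_length = smoothing, seed = seed)
  map <- generate_landscape(cfg)
  roads <- generate_roads(cfg, seed = seed + 1)
  stack <- build_covariates(map, roads, window_radius)
  list(cfg = cfg, map = map, roads = roads, stack = stack)
}

# simulate a full use-availability table from a true RSF over `world`
make_table <- function(world, rsf, n_ind = 4, n_points = 60, ratio = 5,
                       hr_radius = 400, seed = 1, scale = "study_area") {
  inds <- simulate_individuals(n_ind, c(ceiling(n_ind / 2), floor(n_ind / 2)),
                               world$map, mean_hr_area = pi * hr_radius^2,
                               seed = seed, n_points_mean = n_points,
                               n_points_sd = max(1, round(n_points / 10)))
  tel <- simulate_telemetry(inds, world$stack, rsf, seed = seed + 100)
  dom <- clip_region(study_area(tel, hr_radius), as_region(world$map))
  tab <- build_table(tel, world$stack, dom, ratio = ratio, scale = scale,
                     seed = seed + 200)
  list(individuals = inds, telemetry = tel, domain = dom, table = tab)
}

# per-map-sd standardized log-linear coefficients (effect per 1 sd of the
# covariate over the landscape)
standardized_coefs <- function(stack, effects) {
  sds <- vapply(stack$grids[names(effects)],
                function(g) stats::sd(as.vector(g)), numeric(1))
  effects / sds
}

# ---- independent oracles ----

# all-pairs minimum center distance to cells of class k
brute_distance_to_class <- function(map, class) {
  k <- match(class, map$levels)
  cs <- map$geom$cell_size
  tgt <- which(map$classes == k, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(map$classes), ncol(map$classes))
  for (r in seq_len(nrow(map$classes))) {
    for (c in seq_len(ncol(map$classes))) {
      out[r, c] <- sqrt(min((tgt[, 1] - r)^2 + (tgt[, 2] - c)^2)) * cs
    }
  }
  out
}

# per-cell loop evenness oracle (clipped circular window, n fixed at 5)
brute_evenness <- function(map, window_radius) {
  cs <- map$geom$cell_size
  nr <- nrow(map$classes); nc <- ncol(map$classes)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      cnt <- numeric(5)
      for (rr in seq_len(nr)) {
        for (cc in seq_len(nc)) {
          if (((rr - r)^2 + (cc - c)^2) * cs^2 <= window_radius^2)
            cnt[map$classes[rr, cc]] <- cnt[map$classes[rr, cc]] + 1
        }
      }
      p <- cnt / sum(cnt)
      out[r, c] <- -sum(ifelse(p > 0, p * log(p), 0)) / log(5)
    }
  }
  out
}

# all-pairs AUC with explicit tie handling
brute_auc <- function(scores, labels) {
  used <- scores[labels == "used"]; avail <- scores[labels == "available"]
  tot <- 0
  for (u in used) for (a in avail)
    tot <- tot + (u > a) + 0.5 * (u == a)
  tot / (length(used) * length(avail))
}

# union area of two equal discs, closed form
two_disc_union_area <- function(d, r) {
  if (d >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  2 * pi * r^2 - lens
}

# independently coded 100-point additive regression RMSE (explicit normal
# equations, no lm): used to cross-check interaction_rmse
brute_additive_rmse <- function(pred, v1, v2) {
  A <- cbind(1, v1, v2)
  beta <- solve(t(A) %*% A, t(A) %*% pred)
  sqrt(mean((pred - A %*% beta)^2))
}
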