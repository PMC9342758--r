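# stated-world scenario builders shared by the acceptance suite and the
# acceptance report script. Scales are desk-sized stand-ins for the field
# study the package emulates; coefficients are standardized per local
# covariate SD so "strong" means ~2 SD per unit effect.

# landscape + covariates world at the acceptance scale
acceptance_world <- function(seed, nr = 150, nc = 150, cell_size = 60,
                             smoothing = 900, window_radius = 600) {
  cfg <- landscape_config(nr, nc, cell_size = cell_size,
                          smoothing_length = smoothing, seed = seed)
  map <- generate_landscape(cfg)
  roads <- generate_roads(cfg, seed = seed + 50)
  list(map = map, roads = roads,
       stack = build_covariates(map, roads, window_radius))
}

# disc availability domains around individual centers, clipped to the map
disc_domains <- function(inds, radius, map) {
  doms <- lapply(seq_len(nrow(inds)), function(i)
    clip_region(study_area(inds[i, c("x", "y")], radius), as_region(map)))
  names(doms) <- inds$id
  doms
}

# threshold-avoidance world (PDP half-rise recovery): animals hard-avoid
# agriculture within 1000 m; centers are placed in usable habitat
threshold_world <- function(seed, n_ind = 4, n_points = 500, radius = 2000) {
  w <- acceptance_world(seed, nr = 200, nc = 200, smoothing = 1500)
  rsf <- rsf_threshold(rules = list(list(covariate = "dist_agriculture",
                                         side = "below", threshold = 1000,
                                         weight = 0)))
  geom <- w$map$geom
  xs <- cell_centers_x_(geom); ys <- cell_centers_y_(geom)
  ok <- which(w$stack$grids$dist_agriculture >= 1200, arr.ind = TRUE)
  cx <- xs[ok[, 2]]; cy <- ys[ok[, 1]]
  ext <- c(radius, geom$n_cols * geom$cell_size - radius)
  keep <- cx > ext[1] & cx < ext[2] & cy > ext[1] & cy < ext[2]
  pick <- with_seed_(seed, sample(which(keep), n_ind))
  inds <- data.frame(id = sprintf("ind%02d", seq_len(n_ind)),
                     sex = rep(c("M", "F"), length.out = n_ind),
                     x = cx[pick], y = cy[pick],
                     availability_radius = radius, n_points = n_points)
  tel <- simulate_telemetry(inds, w$stack, rsf, seed = seed + 20)
  tab <- build_table(tel, w$stack, disc_domains(inds, radius, w$map),
                     ratio = 5, seed = seed + 30)
  list(world = w, individuals = inds, telemetry = tel, table = tab)
}

# product-interaction world: the only signal is a standardized
# agriculture x major-road product term
interaction_world <- function(seed, beta = 2.5, n_ind = 6, n_points = 350,
                              radius = 2000) {
  w <- acceptance_world(seed)
  inds <- simulate_individuals(n_ind, c(ceiling(n_ind / 2), floor(n_ind / 2)),
                               w$map, mean_hr_area = pi * radius^2,
                               seed = seed + 10, n_points_mean = n_points,
                               n_points_sd = 10)
  mom <- local_moments(w, inds, radius, c("dist_agriculture",
                                          "dist_major_road"))
  m1 <- unname(mom$mean[1]); s1 <- unname(mom$sd[1])
  m2 <- unname(mom$mean[2]); s2 <- unname(mom$sd[2])
  rsf <- rsf_log_linear(
    coefs = c(dist_agriculture = -beta * m2 / (s1 * s2),
              dist_major_road = -beta * m1 / (s1 * s2)),
    interactions = list(list(pair = c("dist_agriculture", "dist_major_road"),
                             coef = beta / (s1 * s2))))
  tel <- simulate_telemetry(inds, w$stack, rsf, seed = seed + 20)
  tab <- build_table(tel, w$stack, disc_domains(inds, radius, w$map),
                     ratio = 5, seed = seed + 30)
  list(world = w, table = tab)
}

# 27-individual world under strong two-covariate log-linear selection
# (used-point counts scaled down from the field study's ~258 per animal to
# keep leave-one-individual-out refits inside the test budget)
loio_world <- function(seed, n_points = 50, radius = 1500) {
  w <- acceptance_world(seed)
  inds <- simulate_individuals(27, c(14, 13), w$map,
                               mean_hr_area = pi * radius^2,
                               seed = seed + 10, n_points_mean = n_points,
                               n_points_sd = 5)
  sds <- vapply(w$stack$grids[c("dist_agriculture", "dist_forest_signed")],
                function(g) stats::sd(as.vector(g)), numeric(1))
  rsf <- rsf_log_linear(coefs = c(dist_agriculture = unname(2 / sds[1]),
                                  dist_forest_signed = unname(-2 / sds[2])))
  tel <- simulate_telemetry(inds, w$stack, rsf, seed = seed + 20)
  build_table(tel, w$stack, disc_domains(inds, radius, w$map),
              ratio = 5, seed = seed + 30)
}

# shuffle labels within each individual (decouples covariates from use)
shuffle_labels <- function(tab, seed) {
  with_seed_(seed, {
    tab$label <- unsplit(lapply(split(tab$label, tab$id), sample), tab$id)
    tab
  })
}

# first grid value whose dependence exceeds the midpoint between the curve's
# minimum and its plateau (mean over the last quarter of the grid)
pdp_half_rise <- function(pd) {
  dep <- pd$dependence; g <- pd$grid
  plateau <- mean(dep[seq(ceiling(0.75 * length(g)), length(g))])
  half <- min(dep) + 0.5 * (plateau - min(dep))
  g[which(dep >= half)[1]]
}

local_moments <- function(w, inds, radius, covs) {
  geom <- w$map$geom
  cc <- expand.grid(x = cell_centers_x_(geom), y = cell_centers_y_(geom))
  ok <- rep(FALSE, nrow(cc))
  for (i in seq_len(nrow(inds)))
    ok <- ok | ((cc$x - inds$x[i])^2 + (cc$y - inds$y[i])^2 <= radius^2)
  z <- extract_covariates(w$stack, cc$x[ok], cc$y[ok])[, covs, drop = FALSE]
  list(mean = vapply(z, mean, numeric(1)), sd = vapply(z, stats::sd, numeric(1)))
}

# thin wrappers over package internals so the acceptance script (which only
# attaches the installed package) can share this file unchanged
cell_centers_x_ <- function(geom) selscape:::cell_centers_x(geom)
cell_centers_y_ <- function(geom) selscape:::cell_centers_y(geom)
with_seed_ <- function(seed, code) selscape:::with_seed(seed, code)
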