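test_that("distance_to_class matches unit geometry and the brute-force oracle", {
  # 3x3: center cell agriculture, rest forest, cell_size 30
  cls <- matrix(1, 3, 3); cls[2, 2] <- 2
  map <- map_from_matrix(cls, cell_size = 30)
  d <- distance_to_class(map, "agriculture")
  expect_equal(d[2, 2], 0)
  expect_equal(d[1, 2], 30)           # orthogonal neighbour
  expect_equal(d[1, 1], 30 * sqrt(2)) # diagonal neighbour

  map30 <- random_map(30, 30, seed = 7)
  for (cl in c("forest", "grassland", "developed")) {
    expect_lt(max(abs(distance_to_class(map30, cl) -
                      brute_distance_to_class(map30, cl))), 1e-9)
  }
  expect_error(distance_to_class(map_from_matrix(matrix(1, 4, 4)), "water"),
               "absent")
})

test_that("signed forest distance follows the negative-inside convention", {
  map <- random_map(30, 30, seed = 8)
  s <- signed_forest_distance(map)
  forest <- map$classes == 1
  # sign partition: negative exactly on forest cells, positive elsewhere
  expect_true(all(s[forest] < 0))
  expect_true(all(s[!forest] > 0))
  expect_false(anyNA(s))
  # brute force: two all-pairs scans with a sign flip
  d_f <- brute_distance_to_class(map, "forest")
  inv <- map
  inv$classes <- matrix(ifelse(map$classes == 1, 2L, 1L), 30) # non-forest as class 1
  d_nf <- brute_distance_to_class(inv, "forest")
  expect_lt(max(abs(s - ifelse(forest, -d_nf, d_f))), 1e-9)

  expect_error(signed_forest_distance(map_from_matrix(matrix(1, 4, 4))),
               "degenerate")
})

test_that("distance grids scale exactly with cell size", {
  m1 <- random_map(15, 15, cell_size = 30, seed = 3)
  m2 <- m1; m2$geom$cell_size <- 60
  expect_equal(distance_to_class(m2, "agriculture"),
               2 * distance_to_class(m1, "agriculture"))
  expect_equal(signed_forest_distance(m2), 2 * signed_forest_distance(m1))
})

test_that("road distances match point geometry and a densified oracle", {
  geom <- selscape:::grid_geometry(10, 10, 30)
  # vertical road at x = 150: cell centers at x = 135, 165, ... -> col 10 is 135 m
  vroad <- structure(list(roads = list(list(
    coords = cbind(x = c(150, 150), y = c(0, 300)), class = "major"))),
    class = "road_network")
  d <- distance_to_roads(geom, vroad, "major")
  expect_equal(d[1, 10], 285 - 150) # center x = 285
  expect_equal(d[1, 5], 150 - 135)  # center x = 135

  # a cell center on a road vertex -> 0
  onv <- structure(list(roads = list(list(
    coords = cbind(x = c(15, 200), y = c(15, 230)), class = "minor"))),
    class = "road_network")
  expect_equal(distance_to_roads(geom, onv, "minor")[1, 1], 0)

  # densified-sampling oracle on 2 random polylines, 20x20 frame
  set.seed(5)
  g20 <- selscape:::grid_geometry(20, 20, 30)
  mk <- function() cbind(x = runif(4, 0, 600), y = runif(4, 0, 600))
  net <- structure(list(roads = list(list(coords = mk(), class = "major"),
                                     list(coords = mk(), class = "major"))),
                   class = "road_network")
  d <- distance_to_roads(g20, net, "major")
  dense <- do.call(rbind, lapply(net$roads, function(rd) {
    do.call(rbind, lapply(seq_len(nrow(rd$coords) - 1), function(i) {
      a <- rd$coords[i, ]; b <- rd$coords[i + 1, ]
      len <- sqrt(sum((b - a)^2))
      t <- seq(0, 1, length.out = max(2, ceiling(len)))
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    }))
  }))
  xs <- selscape:::cell_centers_x(g20); ys <- selscape:::cell_centers_y(g20)
  for (probe in list(c(3, 17), c(11, 2), c(20, 20))) {
    bf <- min(sqrt((dense[, 1] - xs[probe[2]])^2 +
                   (dense[, 2] - ys[probe[1]])^2))
    expect_lt(abs(d[probe[1], probe[2]] - bf), 1)
  }

  # absent class: sentinel = map diagonal, logged
  expect_message(ds <- distance_to_roads(g20, vroad, "minor"), "sentinel")
  expect_true(all(ds == sqrt(2) * 600))
})

test_that("evenness formula endpoints and reference value", {
  expect_equal(evenness_index(c(1, 0, 0, 0, 0)), 0)
  expect_equal(evenness_index(rep(0.2, 5)), 1)
  expect_equal(evenness_index(c(0.54, 0.35, 0.04, 0.02, 0.05)), 0.6567,
               tolerance = 1e-4)
})

test_that("moving-window evenness equals the per-cell loop oracle", {
  map <- random_map(20, 20, cell_size = 30, seed = 11)
  he <- evenness(map, 100)
  expect_true(all(he >= 0 & he <= 1))
  expect_lt(max(abs(he - brute_evenness(map, 100))), 1e-9)
  # single-class window -> 0
  uni <- map_from_matrix(matrix(3L, 10, 10))
  expect_true(all(evenness(uni, 60) == 0))
  expect_error(evenness(map, 10), "window_radius")
})

test_that("distance triangle sanity: min of two class distances bounds the union", {
  map <- random_map(25, 25, seed = 13)
  da <- distance_to_class(map, "agriculture")
  dg <- distance_to_class(map, "grassland")
  both <- map
  both$classes <- matrix(ifelse(map$classes %in% c(2, 3), 2L, 1L), 25)
  both$classes[cbind(1:2, 1:2)] <- 1:2
  d_union <- brute_distance_to_class(both, "agriculture")
  expect_true(all(pmin(da, dg) >= d_union - 1e-9))
})

test_that("extraction uses the containing cell and flags outsiders", {
  map <- random_map(10, 12, cell_size = 30, seed = 2)
  net <- generate_roads(landscape_config(10, 12), 1)
  stack <- build_covariates(map, net, 60)
  # exact center
  z <- extract_covariates(stack, 45, 75) # col 2, row 3
  expect_equal(z$evenness, stack$grids$evenness[3, 2])
  # 1 mm inside the top-right corner -> edge cell
  z2 <- extract_covariates(stack, 360 - 1e-3, 300 - 1e-3)
  expect_equal(z2$dist_agriculture, stack$grids$dist_agriculture[10, 12])
  # index-arithmetic oracle on 100 random points
  set.seed(9)
  px <- runif(100, 0, 360); py <- runif(100, 0, 300)
  z3 <- extract_covariates(stack, px, py)
  row <- floor(py / 30) + 1; col <- floor(px / 30) + 1
  expect_equal(z3$dist_water, stack$grids$dist_water[cbind(row, col)])
  expect_error(extract_covariates(stack, -5, 10), "index 1")
})

test_that("covariate stack IO round-trips", {
  w <- make_world(seed = 3, nr = 20, nc = 20, smoothing = 90,
                  window_radius = 90)
  dir <- file.path(tempdir(), "stackio")
  write_covariates(w$stack, dir)
  back <- read_covariates(dir)
  expect_identical(names(back$grids), names(w$stack$grids))
  for (nm in names(back$grids))
    expect_equal(back$grids[[nm]], w$stack$grids[[nm]], tolerance = 1e-5)
})
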