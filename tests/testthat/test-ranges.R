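test_that("closed-form geometry matches printed reference values", {
  expect_equal(round(radius_from_area(135.0e6)), 6555)
  expect_equal(radius_from_area(0), 0)
  expect_equal(radius_from_area(pi * 1e6), 1000)
  expect_error(radius_from_area(-1), "nonnegative")
  expect_equal(round(circle_area_ha(94), 1), 2.8)
  expect_equal(circle_area_ha(0), 0)
  expect_equal(round(circle_area_ha(100), 4), 3.1416)
})

test_that("study_area buffer-dissolve has exact union geometry", {
  r <- 6555
  one <- study_area(data.frame(x = 0, y = 0), r)
  expect_equal(one$n_polygons, 1)
  expect_equal(one$area, pi * r^2, tolerance = 1e-9)
  expect_equal(one$area / 1e6, 135.0, tolerance = 1e-3)

  # two points separated by more than 2r: disjoint discs
  two <- study_area(data.frame(x = c(0, 3 * r), y = c(0, 0)), r)
  expect_equal(two$n_polygons, 2)
  expect_equal(two$area, 2 * pi * r^2, tolerance = 1e-9)

  # coincident points dissolve to one disc
  co <- study_area(data.frame(x = c(5, 5), y = c(7, 7)), r)
  expect_equal(co$n_polygons, 1)
  expect_equal(co$area, pi * r^2, tolerance = 1e-9)

  # overlapping pair vs the closed-form two-disc union area
  for (d in c(0.3, 1.0, 1.7)) {
    ov <- study_area(data.frame(x = c(0, d * r), y = c(0, 0)), r)
    expect_equal(ov$n_polygons, 1)
    expect_equal(ov$area, two_disc_union_area(d * r, r), tolerance = 1e-9)
  }
})

test_that("study_area area never shrinks as points are added", {
  set.seed(12)
  pts <- data.frame(x = runif(15, 0, 4000), y = runif(15, 0, 4000))
  areas <- vapply(3:15, function(k) study_area(pts[1:k, ], 800)$area,
                  numeric(1))
  expect_true(all(diff(areas) >= -1e-9))
})

test_that("study_area containment and rings are consistent", {
  set.seed(3)
  pts <- data.frame(x = runif(6, 0, 2000), y = runif(6, 0, 2000))
  sa <- study_area(pts, 500)
  expect_true(all(region_contains(sa, pts$x, pts$y)))
  # ring vertices lie on some disc boundary (distance r from a center)
  for (ring in sa$rings) {
    dmin <- apply(ring, 1, function(p)
      min(sqrt((pts$x - p[1])^2 + (pts$y - p[2])^2)))
    expect_lt(max(abs(dmin - 500)), 1)
  }
  # discretized-ring area agrees with the exact arc area to 0.1%
  ring_area <- sum(vapply(sa$rings, function(rg) {
    x <- rg[, 1]; y <- rg[, 2]
    sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  }, numeric(1)))
  expect_equal(ring_area, sa$area, tolerance = 1e-3)
})

test_that("plug-in bandwidth is sane, equivariant, and guarded", {
  set.seed(7)
  pts <- data.frame(x = rnorm(1000), y = rnorm(1000))
  H <- plugin_bandwidth(pts)
  # loose normal-scale sanity: diagonal within a factor 2 of var * n^(-1/3)
  for (k in 1:2) {
    ref <- stats::var(pts[[k]]) * 1000^(-1 / 3)
    expect_gt(H[k, k], ref / 2)
    expect_lt(H[k, k], ref * 2)
  }
  expect_equal(H[1, 2], 0)
  # affine equivariance: scaling points by 10 scales H by 100
  H10 <- plugin_bandwidth(pts * 10)
  expect_equal(H10, 100 * H, tolerance = 1e-9)
  # preconditions
  expect_error(plugin_bandwidth(pts[1:5, ]), "10 points")
  collin <- data.frame(x = 1:20, y = 2 * (1:20) + 3)
  expect_error(plugin_bandwidth(collin), "singular")
})

test_that("kernel home range is calibrated against the Gaussian ellipse", {
  set.seed(21)
  pts <- data.frame(x = rnorm(2000), y = rnorm(2000))
  hr <- kde_home_range(pts, 0.95, n_grid = 200)
  expect_gte(hr$mass, 0.93); expect_lte(hr$mass, 0.97)
  expect_equal(hr$area, pi * qchisq(0.95, 2), tolerance = 0.15)
  expect_true(all(eigen(hr$bandwidth)$values > 0))
})

test_that("isopleth masses stay calibrated and levels nest", {
  set.seed(5)
  for (s in 1:5) {
    pts <- data.frame(x = rnorm(300, sd = 2), y = rnorm(300))
    hr95 <- kde_home_range(pts, 0.95, n_grid = 100)
    expect_gte(hr95$mass, 0.93); expect_lte(hr95$mass, 0.97)
    hr75 <- kde_home_range(pts, 0.75, n_grid = 100)
    hr50 <- kde_home_range(pts, 0.50, n_grid = 100)
    # superlevel thresholds decrease with level, so the sets nest
    expect_gt(hr50$threshold, hr75$threshold)
    expect_gt(hr75$threshold, hr95$threshold)
    expect_true(all(hr95$mask[hr50$mask]))
    expect_true(all(hr95$mask[hr75$mask]))
  }
})

test_that("well-separated clusters yield disjoint home-range polygons", {
  set.seed(9)
  pts <- data.frame(x = c(rnorm(200), rnorm(200, 30)),
                    y = c(rnorm(200), rnorm(200, 30)))
  hr <- kde_home_range(pts, 0.95, n_grid = 150)
  expect_gte(hr$n_polygons, 2)
  expect_gte(length(hr$rings), 2)
  # containment follows the mask
  expect_true(all(region_contains(hr, c(0, 30), c(0, 30))))
  expect_false(any(region_contains(hr, 15, 15)))
})

test_that("region GeoJSON export writes valid polygons", {
  sa <- study_area(data.frame(x = c(0, 600), y = c(0, 0)), 500)
  p <- file.path(tempdir(), "sa.geojson")
  write_region_geojson(sa, p)
  gj <- jsonlite::read_json(p)
  expect_identical(gj$type, "FeatureCollection")
  g <- gj$features[[1]]$geometry
  expect_true(g$type %in% c("Polygon", "MultiPolygon"))

  set.seed(2)
  hr <- kde_home_range(data.frame(x = rnorm(100), y = rnorm(100)),
                       n_grid = 80, id = "i1")
  hp <- file.path(tempdir(), "hr.geojson")
  write_region_geojson(hr, hp)
  meta <- jsonlite::read_json(paste0(hp, ".meta.json"), simplifyVector = TRUE)
  expect_equal(meta$iso_level, 0.95)
  expect_gte(meta$mass, 0.93)
})
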