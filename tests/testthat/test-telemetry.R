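test_that("individual simulation honours counts, radius and determinism", {
  # 14 km map so a 6555 m availability radius fits
  big <- map_from_matrix(matrix(1L, 140, 140), cell_size = 100)
  inds <- simulate_individuals(27, c(14, 13), big, mean_hr_area = 135.0e6,
                               seed = 4)
  expect_equal(sum(inds$sex == "M"), 14)
  expect_equal(sum(inds$sex == "F"), 13)
  expect_equal(round(inds$availability_radius[1]), 6555)
  expect_true(all(inds$n_points >= 30))
  expect_identical(inds, simulate_individuals(27, c(14, 13), big,
                                              mean_hr_area = 135.0e6, seed = 4))
  # margin violation
  small <- map_from_matrix(matrix(1L, 20, 20), cell_size = 30)
  expect_error(simulate_individuals(3, c(2, 1), small, mean_hr_area = 135.0e6),
               "extent")
})

test_that("uniform RSF yields uniform used points over the disc", {
  w <- make_world(seed = 2, nr = 80, nc = 80, smoothing = 150,
                  window_radius = 120)
  ind <- data.frame(id = "i1", sex = "F", x = 1200, y = 1200,
                    availability_radius = 600, n_points = 2000)
  used <- sample_used_points(ind, w$stack, rsf_log_linear(), seed = 5)
  expect_equal(nrow(used), 2000)
  # Monte-Carlo oracle: 10 000 uniform disc samples
  set.seed(99)
  r <- 600 * sqrt(runif(10000)); th <- runif(10000, 0, 2 * pi)
  ref <- extract_covariates(w$stack, 1200 + r * cos(th), 1200 + r * sin(th))
  z <- extract_covariates(w$stack, used$x, used$y)
  for (nm in c("dist_agriculture", "dist_forest_signed", "evenness")) {
    std_diff <- (mean(z[[nm]]) - mean(ref[[nm]])) / stats::sd(ref[[nm]])
    expect_lt(abs(std_diff), 0.1)
  }
})

test_that("hard-threshold avoidance excludes the forbidden band", {
  # striped map: agriculture on the left, forest on the right, so the
  # availability disc straddles the 500 m avoidance boundary
  cls <- matrix(1L, 80, 80)
  cls[, 1:25] <- 2L; cls[, 26] <- 3L; cls[, 27] <- 4L; cls[, 28] <- 5L
  map <- map_from_matrix(cls, cell_size = 30)
  roads <- generate_roads(landscape_config(80, 80), 1)
  stack <- build_covariates(map, roads, 120)
  w <- list(map = map, stack = stack)
  rsf <- rsf_threshold(rules = list(list(covariate = "dist_agriculture",
                                         side = "below", threshold = 500,
                                         weight = 0)))
  ind <- data.frame(id = "i1", sex = "M", x = 1500, y = 1200,
                    availability_radius = 900, n_points = 200)
  used <- sample_used_points(ind, w$stack, rsf, seed = 8)
  z <- extract_covariates(w$stack, used$x, used$y)
  expect_true(all(z$dist_agriculture >= 500))
  # determinism
  expect_identical(used, sample_used_points(ind, w$stack, rsf, seed = 8))
})

test_that("telemetry conserves counts across individuals", {
  w <- make_world(seed = 4, nr = 60, nc = 60, smoothing = 150,
                  window_radius = 120)
  inds <- simulate_individuals(3, c(2, 1), w$map, mean_hr_area = pi * 300^2,
                               seed = 1, n_points_mean = 40, n_points_sd = 5)
  tel <- simulate_telemetry(inds, w$stack, rsf_log_linear(), seed = 2)
  expect_equal(nrow(tel), sum(inds$n_points))
  expect_identical(sort(unique(tel$id)), sort(inds$id))
})

test_that("location error has the configured mean displacement", {
  geom <- selscape:::grid_geometry(1000, 1000, 100) # huge: no boundary redraws
  rec <- data.frame(id = "a", sex = "M",
                    x = rep(50000, 10000), y = rep(50000, 10000))
  out <- apply_location_error(rec, 94, geom, seed = 3)
  disp <- sqrt((out$x - rec$x)^2 + (out$y - rec$y)^2)
  expect_gte(mean(disp), 91)
  expect_lte(mean(disp), 97)
  # sd = 0 leaves records untouched; same seed reproduces
  expect_identical(apply_location_error(rec, 0, geom, seed = 1), rec)
  expect_identical(out, apply_location_error(rec, 94, geom, seed = 3))
})

test_that("a negative coefficient shifts used points toward forest", {
  w <- make_world(seed = 6, nr = 80, nc = 80, smoothing = 200,
                  window_radius = 120)
  coefs <- standardized_coefs(w$stack, c(dist_forest_signed = -1))
  ind <- data.frame(id = "i1", sex = "F", x = 1200, y = 1200,
                    availability_radius = 700, n_points = 2000)
  used <- sample_used_points(ind, w$stack, rsf_log_linear(coefs = coefs),
                             seed = 7)
  z_used <- extract_covariates(w$stack, used$x, used$y)
  avail <- sample_available(rect_region(500, 1900, 500, 1900), 2000, seed = 8)
  keep <- (avail$x - 1200)^2 + (avail$y - 1200)^2 <= 700^2
  z_avail <- extract_covariates(w$stack, avail$x[keep], avail$y[keep])
  tt <- t.test(z_used$dist_forest_signed, z_avail$dist_forest_signed,
               alternative = "less")
  expect_lt(tt$p.value, 0.01)
})

test_that("telemetry and RSF persistence round-trip", {
  rec <- data.frame(id = c("a", "b"), sex = c("M", "F"),
                    x = c(10.5, 20.25), y = c(30, 40))
  p <- file.path(tempdir(), "tel.csv")
  write_telemetry(rec, p)
  expect_equal(read_telemetry(p), rec)

  rsf <- rsf_log_linear(0.5, c(dist_agriculture = 0.002, evenness = -1),
                        sex_coef = 0.1,
                        interactions = list(list(pair = c("dist_agriculture",
                                                          "evenness"),
                                                 coef = 0.3)))
  yp <- file.path(tempdir(), "rsf.yaml")
  write_rsf(rsf, yp)
  back <- read_rsf(yp)
  z <- data.frame(dist_agriculture = c(0, 500), evenness = c(0.2, 0.8),
                  sex_male = c(1, 0))
  expect_equal(rsf_weight(back, z), rsf_weight(rsf, z))

  thr <- rsf_threshold(2, list(list(covariate = "evenness", side = "above",
                                    threshold = 0.5, weight = 0.25)))
  write_rsf(thr, yp)
  expect_equal(rsf_weight(read_rsf(yp), z), rsf_weight(thr, z))
})
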