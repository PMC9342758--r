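# oracle prediction functions are injected in place of a fitted forest to
# give closed-form expectations

test_that("partial dependence reproduces closed-form oracles", {
  set.seed(1)
  tab <- data.frame(label = rep(c("used", "available"), 50),
                    z1 = runif(100), z2 = runif(100))
  # identity oracle: PDP of z1 is the identity on its grid
  pd <- partial_dependence(function(df) df$z1, tab, "z1", n_grid = 15)
  expect_equal(pd$dependence, pd$grid, tolerance = 1e-12)
  expect_true(all(diff(pd$grid) > 0))

  # a model ignoring the predictor gives a flat curve
  flat <- partial_dependence(function(df) df$z2 * 2, tab, "z1", n_grid = 10)
  expect_lt(diff(range(flat$dependence)), 1e-12)

  # contract: n_grid points; constant predictor warns
  expect_equal(nrow(partial_dependence(function(df) df$z1, tab, "z1",
                                       n_grid = 5)), 5)
  tab$const <- 3
  expect_warning(partial_dependence(function(df) df$z1, tab, "const",
                                    n_grid = 5), "constant")
})

test_that("PDP of a real forest stays within [0, 1]", {
  set.seed(3)
  tab <- data.frame(label = rep(c("used", "available"), each = 150),
                    x1 = c(rnorm(150, 1), rnorm(150)), x2 = rnorm(300))
  fit <- fit_forest(tab, forest_config(40, 1, 0.623, seed = 2))
  for (p in c("x1", "x2")) {
    pd <- partial_dependence(fit, tab, p, n_grid = 12)
    expect_true(all(pd$dependence >= 0 & pd$dependence <= 1))
  }
})

test_that("interaction RMSE separates additive from multiplicative surfaces", {
  set.seed(4)
  tab <- data.frame(label = rep(c("used", "available"), 100),
                    z1 = rnorm(200), z2 = rnorm(200), z3 = rnorm(200))
  # additive linear oracle: residual is numerically zero
  expect_lt(interaction_rmse(function(df) df$z1 + df$z2, tab,
                             c("z1", "z2")), 1e-10)
  # multiplicative oracle: positive, and equal to an independently coded
  # brute-force regression over the same 100 combinations
  calls <- new.env(); calls$n <- NULL
  oracle <- function(df) { calls$n <- c(calls$n, nrow(df)); df$z1 * df$z2 }
  got <- interaction_rmse(oracle, tab, c("z1", "z2"), n_bins = 10)
  expect_gt(got, 0)
  expect_equal(calls$n, 100) # exactly 100 evaluated combinations
  qmid <- function(x) {
    e <- quantile(x, seq(0, 1, length.out = 11), names = FALSE)
    (e[-1] + e[-11]) / 2
  }
  comb <- expand.grid(a = qmid(tab$z1), b = qmid(tab$z2))
  expect_equal(got, brute_additive_rmse(comb$a * comb$b, comb$a, comb$b),
               tolerance = 1e-9)
  # binning contract
  expect_error(interaction_rmse(oracle, tab, c("z1", "z1")), "distinct|pair")
  tab$binary <- rep(0:1, 100)
  expect_error(interaction_rmse(oracle, tab, c("z1", "binary")), "cannot bin")
  expect_silent(interaction_rmse(function(df) df$z1, tab, c("z1", "binary"),
                                 allow_discrete = TRUE))
})

test_that("max-drop cutoff arithmetic and tie rule", {
  expect_equal(selscape:::max_drop_cut(c(10, 9, 2, 1)), 2L)
  expect_equal(selscape:::max_drop_cut(c(5, 5, 5, 5)), 1L)
  expect_equal(selscape:::max_drop_cut(c(7, 1)), 1L)
})

test_that("rank_interactions covers all pairs and flags a prefix", {
  set.seed(5)
  tab <- data.frame(label = rep(c("used", "available"), 100),
                    z1 = rnorm(200), z2 = rnorm(200), z3 = rnorm(200))
  ir <- rank_interactions(function(df) df$z1 * df$z2 + df$z3, tab,
                          predictors = c("z1", "z2", "z3"))
  expect_equal(nrow(ir), 3)
  expect_identical(ir$rank, 1:3)
  expect_identical(sort(c(ir$var1[1], ir$var2[1])), c("z1", "z2"))
  expect_true(ir$retained[1])
  # retained pairs form a prefix of the descending order
  expect_true(all(diff(ir$retained) <= 0))
  expect_true(all(diff(ir$rmse) <= 1e-12))
})

test_that("max-drop retains no false strong interactions under additive truth", {
  # additive-only true selection: any retained pair should look like the
  # permuted-label null; count retained pairs exceeding the null's max RMSE
  false_strong <- vapply(1:10, function(s) {
    w <- make_world(seed = s, nr = 60, nc = 60, smoothing = 150,
                    window_radius = 120)
    coefs <- standardized_coefs(w$stack, c(dist_agriculture = 1,
                                           dist_forest_signed = -1))
    mt <- make_table(w, rsf_log_linear(coefs = coefs), n_ind = 3,
                     n_points = 80, ratio = 5, hr_radius = 400, seed = s * 31)
    fit <- fit_forest(mt$table, forest_config(50, 3, 0.623, seed = s))
    ir <- rank_interactions(fit, mt$table, n_bins = 10)
    null_tab <- mt$table
    set.seed(s + 500)
    null_tab$label <- sample(null_tab$label)
    null_fit <- fit_forest(null_tab, forest_config(50, 3, 0.623, seed = s))
    null_ir <- rank_interactions(null_fit, null_tab, n_bins = 10)
    sum(ir$retained & ir$rmse > max(null_ir$rmse))
  }, numeric(1))
  expect_gte(sum(false_strong <= 3), 8)
})

test_that("projection matches pointwise re-extraction and stays bounded", {
  w <- make_world(seed = 7, nr = 50, nc = 50, smoothing = 150,
                  window_radius = 120)
  set.seed(2)
  used <- data.frame(id = rep(c("a", "b", "c"), each = 25),
                     sex = rep(c("M", "F", "M"), each = 25),
                     x = runif(75, 100, 1400), y = runif(75, 100, 1400))
  tab <- build_table(used, w$stack, as_region(w$map), 5, seed = 3)
  fit <- fit_forest(tab, forest_config(30, 3, 0.623, seed = 1))
  pr <- project_map(fit, w$stack)
  expect_true(all(pr$values >= 0 & pr$values <= 1))
  expect_equal(dim(pr$values), dim(w$map$classes))
  # 100 random cells vs predict_propensity averaged over sexes
  set.seed(4)
  rows <- sample(50, 10); cols <- sample(50, 10)
  for (k in 1:10) {
    cell <- as.data.frame(lapply(w$stack$grids, function(g)
      g[rows[k], cols[k]]))
    pm <- predict_propensity(fit, transform(cell, sex_male = 1))
    pf <- predict_propensity(fit, transform(cell, sex_male = 0))
    expect_equal(pr$values[rows[k], cols[k]], (pm + pf) / 2,
                 tolerance = 1e-12)
  }
  # band mismatch is rejected
  bad <- w$stack
  bad$grids$evenness <- NULL
  expect_error(project_map(fit, bad), "match")
})
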