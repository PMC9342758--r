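# forest_model: the used-vs-available ensemble classifier.
#
# Trees are CART-style (Gini) classification trees grown on
# without-replacement subsamples, with mtry predictors tried per split.
# Propensity is the fraction of trees voting "used" (tree vote = leaf
# majority, ties 0.5). OOB error is the misclassification rate (0.5 vote
# threshold) over out-of-bag predictions; class weights are deliberately
# unadjusted despite the used:available imbalance, since propensities are
# read relatively, as in any RSF.

#' Forest configuration
#'
#' @param n_trees number of trees (>= 10)
#' @param mtry predictors tried per split (>= 1, checked against the
#'   predictor count at fit time)
#' @param sample_fraction without-replacement subsample fraction per tree,
#'   in (0, 1). The default 0.623 mirrors the tuning tables of the analysis
#'   this package reimplements (kept as printed there).
#' @param min_node minimum node size to attempt a split
#' @param seed integer seed
#' @return a `forest_config`
#' @export
forest_config <- function(n_trees = 200, mtry = 3, sample_fraction = 0.623,
                          min_node = 5, seed = 1) {
  stopifnot(n_trees >= 10, mtry >= 1, sample_fraction > 0,
            sample_fraction < 1, min_node >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 sample_fraction = sample_fraction,
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "forest_config")
}

# predictor matrix: all numeric columns except bookkeeping ones, plus the
# sex indicator (M = 1). Keeps 8 covariates + sex for standard tables but
# admits extra engineered predictors in tests.
predictor_matrix <- function(table, predictors = NULL) {
  df <- as.data.frame(table)
  if (!is.null(df$sex) && is.null(df$sex_male))
    df$sex_male <- as.numeric(df$sex == "M")
  drop <- c("id", "sex", "label", "scale")
  if (is.null(predictors))
    predictors <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], drop)
  miss <- setdiff(predictors, names(df))
  if (length(miss)) stop("missing predictors: ", paste(miss, collapse = ", "))
  as.matrix(df[, predictors, drop = FALSE])
}

#' Fit the use-availability random forest
#'
#' @param table a `ua_table` (or any data.frame with a `label` column in
#'   \{used, available\} and numeric predictors; a `sex` column is encoded
#'   as a 0/1 male indicator)
#' @param config a [forest_config()]
#' @param predictors optional character vector naming predictor columns
#' @return a `fitted_forest` with `oob_error`, per-row OOB votes and the
#'   tree ensemble
#' @export
fit_forest <- function(table, config = forest_config(), predictors = NULL) {
  stopifnot(inherits(config, "forest_config"))
  df <- as.data.frame(table)
  if (!all(c("used", "available") %in% df$label))
    stop("table must contain both used and available rows")
  X <- predictor_matrix(df, predictors)
  if (config$mtry > ncol(X))
    stop("mtry (", config$mtry, ") exceeds predictor count (", ncol(X), ")")
  y <- as.integer(df$label == "used")
  fit <- cpp_rf_fit(X, y, config$n_trees, config$mtry,
                    config$sample_fraction, config$min_node, config$seed)
  if (any(fit$oob_n == 0))
    stop(sum(fit$oob_n == 0), " row(s) never out-of-bag; ",
         "lower sample_fraction or raise n_trees")
  oob_pred <- as.integer(fit$oob_vote > 0.5)
  structure(list(forest = fit[c("feature", "thr", "left", "right", "value",
                                "tree_start")],
                 inbag = fit$inbag,
                 oob_vote = fit$oob_vote,
                 oob_error = mean(oob_pred != y),
                 predictors = colnames(X),
                 config = config, y = y, n = nrow(X)),
            class = "fitted_forest")
}

#' @export
print.fitted_forest <- function(x, ...) {
  cat("fitted_forest:", x$config$n_trees, "trees, mtry", x$config$mtry,
      ", fraction", x$config$sample_fraction, "| OOB error",
      round(x$oob_error, 4), "\n")
  invisible(x)
}

#' Predict selection propensity
#'
#' Vote fraction of the ensemble, in \[0, 1\].
#'
#' @param fitted a `fitted_forest`
#' @param rows data.frame holding every predictor column (a `sex` column is
#'   accepted in place of `sex_male`)
#' @return numeric vector of propensities
#' @export
predict_propensity <- function(fitted, rows) {
  stopifnot(inherits(fitted, "fitted_forest"))
  X <- predictor_matrix(rows, fitted$predictors)
  cpp_rf_predict(fitted$forest, X)
}

#' Default out-of-bag tuning grid
#'
#' Spans trees \{50, 100, 200, 500\}, mtry \{2, 4, 6, 8\} and subsample
#' fraction \{0.4, 0.623, 0.8\}.
#' @return list of `forest_config`s
#' @export
default_forest_grid <- function() {
  g <- expand.grid(n_trees = c(50, 100, 200, 500), mtry = c(2, 4, 6, 8),
                   fraction = c(0.4, 0.623, 0.8))
  lapply(seq_len(nrow(g)), function(i)
    forest_config(g$n_trees[i], g$mtry[i], g$fraction[i]))
}

#' Tune the forest by out-of-bag error
#'
#' Fits every configuration in the grid under a shared seed and picks the
#' lowest OOB error; ties break toward fewer trees, smaller mtry, then the
#' fraction closest to the 0.623 default.
#'
#' @param table a `ua_table`
#' @param grid list of [forest_config()]s (default [default_forest_grid()])
#' @param seed shared fitting seed
#' @param predictors optional predictor names
#' @return a `tuning_result` with `oob`, `chosen`, `chosen_fit`
#' @export
tune_forest <- function(table, grid = default_forest_grid(), seed = 1,
                        predictors = NULL) {
  stopifnot(length(grid) >= 1)
  fits <- lapply(grid, function(cfg) {
    cfg$seed <- as.integer(seed)
    fit_forest(table, cfg, predictors)
  })
  oob <- vapply(fits, function(f) f$oob_error, numeric(1))
  ord <- order(oob,
               vapply(grid, function(g) g$n_trees, numeric(1)),
               vapply(grid, function(g) g$mtry, numeric(1)),
               vapply(grid, function(g) abs(g$sample_fraction - 0.623),
                      numeric(1)))
  best <- ord[1]
  structure(list(grid = grid, oob = oob, chosen = grid[[best]],
                 chosen_index = best, chosen_fit = fits[[best]]),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  ch <- x$chosen
  cat("tuning_result:", length(x$grid), "configs; chosen", ch$n_trees,
      "trees, mtry", ch$mtry, ", fraction", ch$sample_fraction,
      "(OOB", round(min(x$oob), 4), ")\n")
  invisible(x)
}

#' Permutation variable importance
#'
#' Mean out-of-bag accuracy decrease when the focal predictor is permuted
#' within each tree's OOB rows, averaged over trees (and `n_reps`
#' permutations per tree); predictors ranked descending.
#'
#' @param fitted a `fitted_forest`
#' @param table the table it was fitted on
#' @param n_reps permutations per tree (>= 1)
#' @param seed integer seed for the permutations
#' @return an `importance_table` data.frame: predictor, importance, se, rank
#' @export
permutation_importance <- function(fitted, table, n_reps = 1, seed = 1) {
  stopifnot(inherits(fitted, "fitted_forest"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  X <- predictor_matrix(table, fitted$predictors)
  if (nrow(X) != fitted$n) stop("table does not match the fitted forest")
  per_tree <- cpp_rf_importance(fitted$forest, X, fitted$y, fitted$inbag,
                                as.integer(n_reps), as.integer(seed))
  imp <- rowMeans(per_tree)
  se <- apply(per_tree, 1, stats::sd) / sqrt(ncol(per_tree))
  out <- data.frame(predictor = fitted$predictors, importance = imp, se = se,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"))
}

#' Persist / restore a fitted forest as JSON
#'
#' Self-describing: stores the tree arrays, predictor names, configuration
#' and OOB error under a format version tag (the in-bag matrix is not kept).
#'
#' @param fitted a `fitted_forest`
#' @param path JSON path
#' @export
write_forest <- function(fitted, path) {
  jsonlite::write_json(list(
    format = "selscape-forest-1",
    predictors = fitted$predictors,
    config = unclass(fitted$config),
    oob_error = fitted$oob_error,
    forest = fitted$forest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "selscape-forest-1"))
    stop("unrecognized forest file format")
  fo <- as.list(obj$forest)
  fo$feature <- as.integer(fo$feature); fo$left <- as.integer(fo$left)
  fo$right <- as.integer(fo$right); fo$tree_start <- as.integer(fo$tree_start)
  structure(list(forest = fo, inbag = NULL, oob_vote = NULL,
                 oob_error = obj$oob_error, predictors = obj$predictors,
                 config = do.call(forest_config, as.list(obj$config)),
                 y = NULL, n = NULL),
            class = "fitted_forest")
}
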