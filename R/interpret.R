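# interpret: partial dependence, binned two-way interaction ranking with
# the max-drop cutoff, and the projected selection raster.

# accept either a fitted forest or a raw prediction function(df) -> numeric;
# the latter lets tests inject closed-form oracles
as_predict_fun <- function(object) {
  if (is.function(object)) return(object)
  if (inherits(object, "fitted_forest"))
    return(function(df) predict_propensity(object, df))
  stop("need a fitted_forest or a prediction function")
}

#' Partial dependence of the model on one predictor
#'
#' The grid is `n_grid` equally spaced quantiles (1%--99%) of the predictor
#' in the table; dependence at a grid value g is the mean prediction over
#' all table rows (used + available) with the predictor forced to g and
#' every other column untouched.
#'
#' @param object a `fitted_forest` or a prediction function
#' @param table the use-availability table averaged over
#' @param predictor predictor name
#' @param n_grid number of grid points (>= 5)
#' @return a `pdp_curve` data.frame with `grid` and `dependence`
#' @export
partial_dependence <- function(object, table, predictor, n_grid = 20) {
  stopifnot(n_grid >= 5)
  pf <- as_predict_fun(object)
  df <- as.data.frame(table)
  if (!is.null(df$sex) && is.null(df$sex_male))
    df$sex_male <- as.numeric(df$sex == "M")
  if (is.null(df[[predictor]])) stop("unknown predictor: ", predictor)
  v <- df[[predictor]]
  grid <- unique(stats::quantile(v, probs = seq(0.01, 0.99,
                                                length.out = n_grid),
                                 names = FALSE, type = 7))
  if (length(grid) == 1)
    warning("predictor '", predictor, "' is constant: single-point curve")
  if (inherits(object, "fitted_forest") &&
      predictor %in% object$predictors) {
    # fast path: the forced-column sweep runs inside the tree walker
    X <- predictor_matrix(df, object$predictors)
    dep <- cpp_rf_pdp(object$forest, X,
                      match(predictor, object$predictors) - 1L, grid)
  } else {
    dep <- vapply(grid, function(g) {
      df[[predictor]] <- g
      mean(pf(df))
    }, numeric(1))
  }
  structure(data.frame(grid = grid, dependence = dep),
            class = c("pdp_curve", "data.frame"), predictor = predictor)
}

#' Interaction strength of one predictor pair (binned RMSE)
#'
#' Each variable of the pair is divided into `n_bins` equal-frequency bins
#' (representative value = midpoint of the bin-edge quantiles), yielding
#' `n_bins^2` combinations. With every other predictor held at its table
#' mean (sex at its mean indicator value), the model predicts each
#' combination; the predictions are regressed on the two bin values with no
#' product term, and the root mean squared residual of that additive linear
#' fit is the interaction score.
#'
#' @param object a `fitted_forest` or prediction function
#' @param table the use-availability table
#' @param pair character vector of two distinct predictor names
#' @param n_bins bins per variable (default 10, i.e. 100 combinations)
#' @param allow_discrete if TRUE, a variable with fewer distinct values than
#'   `n_bins` (e.g. the binary sex indicator) is represented by its distinct
#'   values instead of signalling a binning error; [rank_interactions()]
#'   enables this so all pairs of the nine predictors remain rankable
#' @return the RMSE (>= 0); larger means less additive
#' @export
interaction_rmse <- function(object, table, pair, n_bins = 10,
                             allow_discrete = FALSE) {
  stopifnot(length(pair) == 2, pair[1] != pair[2], n_bins >= 2)
  pf <- as_predict_fun(object)
  df <- as.data.frame(table)
  if (!is.null(df$sex) && is.null(df$sex_male))
    df$sex_male <- as.numeric(df$sex == "M")
  bin_values <- function(x, nm) {
    if (length(unique(x)) < n_bins) {
      if (allow_discrete && length(unique(x)) >= 2)
        return(sort(unique(x)))
      stop("predictor '", nm, "' has fewer than ", n_bins,
           " distinct values: cannot bin")
    }
    edges <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                             names = FALSE, type = 7)
    (edges[-1] + edges[-(n_bins + 1)]) / 2
  }
  v1 <- bin_values(df[[pair[1]]], pair[1])
  v2 <- bin_values(df[[pair[2]]], pair[2])
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  base <- as.data.frame(lapply(df[, setdiff(num, c("id", "scale")),
                                  drop = FALSE], mean))
  comb <- expand.grid(a = v1, b = v2)
  newdf <- base[rep(1, nrow(comb)), , drop = FALSE]
  newdf[[pair[1]]] <- comb$a
  newdf[[pair[2]]] <- comb$b
  pred <- pf(newdf)
  fit <- stats::lm(pred ~ comb$a + comb$b)
  sqrt(mean(stats::residuals(fit)^2))
}

#' Rank all two-way interactions with the max-drop cutoff
#'
#' Computes [interaction_rmse()] for every unordered predictor pair, ranks
#' them by descending RMSE, and retains the pairs above the largest drop
#' between consecutive sorted values. If all RMSE are equal (degenerate
#' gap), only the top pair is retained.
#'
#' @param object a `fitted_forest` or prediction function
#' @param table the use-availability table
#' @param predictors predictor names (default: the fitted forest's)
#' @param n_bins bins per variable
#' @return an `interaction_ranking` data.frame: var1, var2, rmse, rank,
#'   retained
#' @export
rank_interactions <- function(object, table, predictors = NULL, n_bins = 10) {
  if (is.null(predictors)) {
    if (!inherits(object, "fitted_forest"))
      stop("predictors must be given when object is a raw function")
    predictors <- object$predictors
  }
  stopifnot(length(predictors) >= 2)
  pairs <- utils::combn(predictors, 2)
  rmse <- vapply(seq_len(ncol(pairs)), function(k)
    interaction_rmse(object, table, pairs[, k], n_bins,
                     allow_discrete = TRUE), numeric(1))
  ord <- order(-rmse)
  out <- data.frame(var1 = pairs[1, ord], var2 = pairs[2, ord],
                    rmse = rmse[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  out$retained <- out$rank <= max_drop_cut(out$rmse)
  structure(out, class = c("interaction_ranking", "data.frame"))
}

# max-drop cutoff on descending-sorted scores: number of leading items kept,
# i.e. the position of the largest drop between consecutive values; all-equal
# scores degenerate to keeping only the top item
max_drop_cut <- function(rmse_desc) {
  gaps <- -diff(rmse_desc)
  if (!length(gaps) || max(gaps) <= 1e-15) 1L else which.max(gaps)
}

#' Project the fitted model over the landscape
#'
#' Predicts the selection propensity of every cell from the covariate stack.
#' Sex has no raster, so each cell is predicted once per sex level and the
#' two propensities averaged.
#'
#' @param fitted a `fitted_forest` trained on the 8 stack covariates + sex
#' @param stack a `covariate_stack`
#' @return a `prediction_raster`: propensity matrix in \[0, 1\] aligned to
#'   the stack
#' @export
project_map <- function(fitted, stack) {
  stopifnot(inherits(fitted, "fitted_forest"),
            inherits(stack, "covariate_stack"))
  need <- setdiff(fitted$predictors, "sex_male")
  if (!setequal(need, names(stack$grids)))
    stop("stack bands do not match the fitted non-sex predictors")
  cells <- as.data.frame(lapply(stack$grids[need], as.vector))
  cells$sex_male <- 1
  p_m <- predict_propensity(fitted, cells)
  cells$sex_male <- 0
  p_f <- predict_propensity(fitted, cells)
  vals <- matrix((p_m + p_f) / 2, stack$geom$n_rows, stack$geom$n_cols)
  structure(list(values = vals, geom = stack$geom),
            class = "prediction_raster")
}

#' Write interpretation artifacts
#'
#' @param x a `pdp_curve`, `interaction_ranking` or `prediction_raster`
#' @param path output path (CSV for tables, ASCII grid for rasters)
#' @export
write_pdp <- function(x, path) {
  df <- as.data.frame(x)
  df$predictor <- attr(x, "predictor")
  write_table_csv(df[, c("predictor", "grid", "dependence")], path)
}

#' @rdname write_pdp
#' @export
write_interactions <- function(x, path) write_table_csv(as.data.frame(x), path)

#' @rdname write_pdp
#' @export
write_prediction_raster <- function(x, path)
  write_ascii_grid(x$values, x$geom, path, digits = 6)
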