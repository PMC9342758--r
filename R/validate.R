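# validate: leave-one-individual-out cross-validation scored by ROC AUC.

#' ROC AUC of scores against used/available labels
#'
#' Mann-Whitney statistic: the probability that a randomly chosen used row
#' scores higher than a randomly chosen available row, counting ties as 1/2
#' (equivalently, the trapezoidal area under the ROC curve). Computed with
#' midranks, exactly equal to all-pairs counting.
#'
#' @param scores numeric scores (higher = more "used")
#' @param labels vector in \{"used", "available"\} (or logical, TRUE = used)
#' @return AUC in \[0, 1\]
#' @export
roc_auc <- function(scores, labels) {
  used <- if (is.logical(labels)) labels else labels == "used"
  n_u <- sum(used); n_a <- sum(!used)
  if (n_u == 0 || n_a == 0)
    stop("both used and available labels required")
  r <- rank(scores)
  (sum(r[used]) - n_u * (n_u + 1) / 2) / (n_u * n_a)
}

#' Leave-one-individual-out cross-validation
#'
#' For each individual: refit the forest on every other individual's rows
#' (same configuration, seed derived as `config$seed + index`), score the
#' held-out individual's used and available rows, and compute their ROC
#' AUC. Individuals whose rows hold a single label class are skipped with a
#' warning and excluded from the summary.
#'
#' @param table a `ua_table` with >= 3 individuals
#' @param config a [forest_config()] held fixed across folds
#' @param predictors optional predictor names
#' @return a `cv_result`: per-individual AUCs, `mean_auc`, `se_auc`
#'   (standard error across individuals), `n_skipped`
#' @export
loio_cv <- function(table, config = forest_config(), predictors = NULL) {
  df <- as.data.frame(table)
  ids <- unique(df$id)
  if (length(ids) < 3) stop("leave-one-individual-out needs >= 3 individuals")
  aucs <- numeric(0)
  kept <- character(0)
  n_skipped <- 0L
  for (i in seq_along(ids)) {
    hold <- df[df$id == ids[i], , drop = FALSE]
    if (length(unique(hold$label)) < 2) {
      warning("individual ", ids[i], " has a single label class: skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    cfg <- config
    cfg$seed <- as.integer(config$seed + i)
    fit <- fit_forest(df[df$id != ids[i], , drop = FALSE], cfg, predictors)
    sc <- predict_propensity(fit, hold)
    aucs <- c(aucs, roc_auc(sc, hold$label))
    kept <- c(kept, ids[i])
  }
  k <- length(aucs)
  structure(list(individual = kept, auc = aucs,
                 mean_auc = mean(aucs),
                 se_auc = if (k > 1) stats::sd(aucs) / sqrt(k) else 0,
                 n_skipped = n_skipped,
                 scale = attr(table, "provenance")$scale %||% NA_character_),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result: mean AUC ", round(x$mean_auc, 3), " +/- ",
      round(x$se_auc, 3), " (SE) over ", length(x$auc), " individuals",
      if (x$n_skipped) paste0(", ", x$n_skipped, " skipped") else "",
      "\n", sep = "")
  invisible(x)
}

#' Write a cross-validation result
#'
#' Per-individual AUCs as CSV plus a JSON summary (`<path>.json`).
#' @param x a `cv_result`
#' @param path CSV path
#' @export
write_cv_result <- function(x, path) {
  write_table_csv(data.frame(individual = x$individual, auc = x$auc), path)
  jsonlite::write_json(list(mean_auc = x$mean_auc, se_auc = x$se_auc,
                            n_skipped = x$n_skipped, scale = x$scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = 10)
  invisible(path)
}
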