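# design: use-availability tables at both selection scales and the
# available-point ratio stabilization diagnostic.
#
# Available points are generated per individual (from its own availability
# domain) and inherit that individual's sex, since sex is a model predictor
# and the per-individual diagnostic needs per-individual available samples.

#' Sample available points uniformly over a region
#'
#' Rejection sampling from the region's bounding box. A degenerate sliver
#' domain (acceptance below 1e-6) is an error.
#'
#' @param domain a region (`study_area`, `home_range`, `rect_region`)
#' @param n number of points (>= 1)
#' @param seed integer seed
#' @return data.frame with columns x, y (exactly `n` in-domain points)
#' @export
sample_available <- function(domain, n, seed = 1) {
  stopifnot(n >= 1)
  bb <- region_bbox(domain)
  with_seed(seed, {
    got_x <- numeric(0); got_y <- numeric(0)
    proposed <- 0
    batch <- max(4 * n, 1000)
    while (length(got_x) < n) {
      px <- stats::runif(batch, bb["xmin"], bb["xmax"])
      py <- stats::runif(batch, bb["ymin"], bb["ymax"])
      keep <- region_contains(domain, px, py)
      got_x <- c(got_x, px[keep]); got_y <- c(got_y, py[keep])
      proposed <- proposed + batch
      if (proposed > 2e6 && length(got_x) / proposed < 1e-6)
        stop("degenerate availability domain: acceptance rate below 1e-6")
    }
    data.frame(x = got_x[seq_len(n)], y = got_y[seq_len(n)])
  })
}

#' Build a use-availability table
#'
#' Per individual, the used rows are its telemetry records and exactly
#' `ratio` times as many available rows are sampled from that individual's
#' availability domain, inheriting its id and sex.
#'
#' @param used telemetry data.frame (id, sex, x, y)
#' @param stack a `covariate_stack`
#' @param domains either a single region shared by all individuals
#'   (study-area scale) or a named list of regions keyed by individual id
#'   (home-range scale)
#' @param ratio available:used ratio (integer >= 1); the analysis this
#'   mirrors settled on 1:10
#' @param scale `"study_area"` or `"home_range"` (a label carried on rows)
#' @param seed base seed; individual i draws with `seed + i`
#' @return a `ua_table` data.frame: id, sex, label, scale, 8 covariates
#' @export
build_table <- function(used, stack, domains, ratio, scale = "study_area",
                        seed = 1) {
  stopifnot(ratio >= 1, scale %in% c("study_area", "home_range"))
  ids <- unique(used$id)
  shared <- inherits(domains, "sa_region")
  rows <- lapply(seq_along(ids), function(i) {
    u <- used[used$id == ids[i], , drop = FALSE]
    if (nrow(u) == 0) stop("individual ", ids[i], " has 0 used points")
    dom <- if (shared) domains else domains[[ids[i]]]
    if (is.null(dom)) stop("no availability domain for individual ", ids[i])
    av <- sample_available(dom, ratio * nrow(u), seed = seed + i)
    zu <- extract_covariates(stack, u$x, u$y)
    za <- extract_covariates(stack, av$x, av$y)
    rbind(
      cbind(data.frame(id = u$id, sex = u$sex, label = "used",
                       scale = scale, stringsAsFactors = FALSE), zu),
      cbind(data.frame(id = ids[i], sex = u$sex[1], label = "available",
                       scale = scale, stringsAsFactors = FALSE), za))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyNA(out)) stop("missing covariate values in use-availability table")
  structure(out, class = c("ua_table", "data.frame"),
            provenance = list(seed = seed, ratio = ratio, scale = scale))
}

#' Available-point ratio stabilization diagnostic
#'
#' For each covariate and individual, the mean and SD of available-point
#' covariate values at each candidate ratio. The selected ratio is the
#' smallest ratio r such that, for every covariate and individual, the
#' relative change of both mean and SD from r to every larger ratio is at
#' most `epsilon` (relative to the larger-ratio value, with an absolute
#' floor of 1 on the denominator to guard near-zero means). If no ratio
#' qualifies the largest is returned with `stabilized = FALSE` and a warning.
#'
#' @param tables named list of `ua_table`s keyed by ratio (e.g. `"1"`, `"2"`,
#'   `"5"`, `"10"`, `"20"`), all over the same individuals
#' @param epsilon relative-change tolerance (default 0.05)
#' @return a `ratio_diagnostic`: per-ratio stats, `selected_ratio`,
#'   `stabilized`
#' @export
ratio_stabilization <- function(tables, epsilon = 0.05) {
  ratios <- sort(as.integer(names(tables)))
  stopifnot(length(ratios) >= 2, !anyNA(ratios))
  ids <- sort(unique(tables[[1]]$id))
  for (tb in tables)
    if (!identical(sort(unique(tb$id)), ids))
      stop("tables hold mismatched individuals")
  covs <- covariate_names()
  stats_df <- do.call(rbind, lapply(ratios, function(r) {
    tb <- tables[[as.character(r)]]
    av <- tb[tb$label == "available", , drop = FALSE]
    do.call(rbind, lapply(ids, function(id) {
      sub <- av[av$id == id, covs, drop = FALSE]
      data.frame(ratio = r, id = id, covariate = covs,
                 mean = vapply(sub, mean, numeric(1)),
                 sd = vapply(sub, stats::sd, numeric(1)),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }))
  if (any(!is.finite(stats_df$mean)) || any(!is.finite(stats_df$sd)))
    stop("non-finite availability statistics")

  rel <- function(a, b) abs(a - b) / pmax(abs(b), 1)
  selected <- NA_integer_
  for (r in ratios[-length(ratios)]) {
    ok <- TRUE
    cur <- stats_df[stats_df$ratio == r, ]
    for (r2 in ratios[ratios > r]) {
      nxt <- stats_df[stats_df$ratio == r2, ]
      # rows align: same (id, covariate) order by construction
      if (any(rel(cur$mean, nxt$mean) > epsilon) ||
          any(rel(cur$sd, nxt$sd) > epsilon)) { ok <- FALSE; break }
    }
    if (ok) { selected <- r; break }
  }
  stabilized <- !is.na(selected)
  if (!stabilized) {
    selected <- max(ratios)
    warning("no ratio stabilized at epsilon = ", epsilon,
            "; falling back to ", selected)
  }
  structure(list(stats = stats_df, selected_ratio = selected,
                 epsilon = epsilon, stabilized = stabilized),
            class = "ratio_diagnostic")
}

#' @export
print.ratio_diagnostic <- function(x, ...) {
  cat("ratio_diagnostic: selected 1:", x$selected_ratio,
      if (!x$stabilized) " (not stabilized)" else "",
      " at epsilon ", x$epsilon, "\n", sep = "")
  invisible(x)
}

#' Write a use-availability table or ratio diagnostic
#' @param x object to write
#' @param path CSV path (diagnostic also writes `<path>.json` summary)
#' @export
write_ua_table <- function(x, path) write_table_csv(as.data.frame(x), path)

#' @rdname write_ua_table
#' @export
write_ratio_diagnostic <- function(x, path) {
  write_table_csv(x$stats, path)
  jsonlite::write_json(list(selected_ratio = x$selected_ratio,
                            epsilon = x$epsilon, stabilized = x$stabilized),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ua_table
#' @export
read_ua_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("ua_table", "data.frame"))
}
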