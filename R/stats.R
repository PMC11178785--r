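#' Replicate-aware summary of one metric in one group
#'
#' SuperPlot convention: cell-level values are first averaged within each
#' biological replicate; the grand mean and SEM are computed across the
#' replicate means, never across cells (cell-level error bars understate
#' biological variability and inflate significance).
#'
#' @param metrics A per-track metrics table from [track_metrics()].
#' @param group Group label to summarize.
#' @param metric Name of the metric column (default `"net_displacement_um"`).
#' @param config A [analysis_config()]; supplies the non-motile threshold
#'   used for `fraction_non_motile`.
#' @return A `group_summary` list: `group`, `metric`, `per_replicate_means`
#'   (named), `grand_mean`, `sem` (`NA` and flagged when fewer than 2
#'   replicates), `sem_defined`, `n_cells`, `n_replicates`,
#'   `fraction_non_motile`.
#' @export
summarize_group <- function(metrics, group, metric = "net_displacement_um",
                            config = analysis_config()) {
  if (!metric %in% names(metrics)) stop("unknown metric: '", metric, "'")
  rows <- metrics[metrics$group == group, , drop = FALSE]
  if (!nrow(rows)) stop("no tracks in group '", group, "'")
  vals <- rows[[metric]]
  rep_means <- c(tapply(vals, rows$replicate_id, mean, na.rm = TRUE))
  n_rep <- length(rep_means)
  sem <- if (n_rep >= 2L) stats::sd(rep_means) / sqrt(n_rep) else NA_real_
  structure(list(
    group = group,
    metric = metric,
    per_replicate_means = rep_means,
    grand_mean = mean(rep_means),
    sem = sem,
    sem_defined = n_rep >= 2L,
    n_cells = nrow(rows),
    n_replicates = n_rep,
    fraction_non_motile =
      mean(rows$net_displacement_um < config$non_motile_threshold)
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s / %s\n", x$group, x$metric))
  cat(sprintf("  grand mean %.4g +/- %s SEM over %d replicate(s), %d cell(s)\n",
              x$grand_mean,
              if (x$sem_defined) sprintf("%.4g", x$sem) else "NA (single replicate)",
              x$n_replicates, x$n_cells))
  cat(sprintf("  fraction non-motile: %.3f\n", x$fraction_non_motile))
  invisible(x)
}

#' Summaries for every group in a metrics table
#'
#' @inheritParams summarize_group
#' @return A data frame, one row per group:
#'   `group, metric, grand_mean, sem, n_replicates, n_cells,
#'   fraction_non_motile`.
#' @export
summarize_cohort <- function(metrics, metric = "net_displacement_um",
                             config = analysis_config()) {
  groups <- unique(metrics$group)
  do.call(rbind, lapply(groups, function(g) {
    s <- summarize_group(metrics, g, metric, config)
    data.frame(group = g, metric = metric, grand_mean = s$grand_mean,
               sem = s$sem, n_replicates = s$n_replicates,
               n_cells = s$n_cells,
               fraction_non_motile = s$fraction_non_motile,
               stringsAsFactors = FALSE)
  }))
}

#' Replicate means of a metric, per group
#'
#' @inheritParams summarize_group
#' @return A data frame `group, replicate_id, value` with one row per
#'   (group, replicate).
#' @export
replicate_means <- function(metrics, metric = "net_displacement_um") {
  if (!metric %in% names(metrics)) stop("unknown metric: '", metric, "'")
  agg <- stats::aggregate(
    metrics[[metric]],
    by = list(group = metrics$group, replicate_id = metrics$replicate_id),
    FUN = mean, na.rm = TRUE
  )
  names(agg)[3] <- "value"
  agg[order(agg$group, agg$replicate_id), , drop = FALSE]
}

#' One-way ANOVA with Tukey multiple comparisons on replicate means
#'
#' The observations are the *replicate means* (n = number of independent
#' experiments), never the individual cells. A one-way fixed-effects ANOVA
#' is fitted across groups and all pairwise contrasts are adjusted by
#' Tukey's honestly-significant-difference procedure using the single pooled
#' within-group variance (the studentized-range distribution).
#'
#' @param rep_means A data frame `group, replicate_id, value` as returned by
#'   [replicate_means()].
#' @return A list with `f_statistic`, `df` (numerator, denominator),
#'   `p_value`, `pairwise` (data frame `comparison, diff, lwr, upr, p_adj`),
#'   and `pooled_variance`. With zero pooled variance the p-values are `NA`
#'   and a warning signals the degeneracy.
#' @export
anova_tukey <- function(rep_means) {
  stopifnot(all(c("group", "value") %in% names(rep_means)))
  groups <- unique(rep_means$group)
  if (length(groups) < 2L) stop("at least 2 groups are required")
  counts <- table(rep_means$group)
  if (any(counts < 2L)) {
    stop("every group needs >= 2 replicate means; offending group(s): ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  d <- data.frame(value = rep_means$value, group = factor(rep_means$group))
  fit <- stats::aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  ms_within <- an["Residuals", "Mean Sq"]
  if (ms_within <= .Machine$double.eps * max(abs(d$value), 1)^2) {
    warning("zero pooled within-group variance; p-values undefined")
    combs <- utils::combn(as.character(sort(unique(d$group))), 2)
    pw <- data.frame(
      comparison = paste(combs[2, ], combs[1, ], sep = "-"),
      diff = NA_real_, lwr = NA_real_, upr = NA_real_, p_adj = NA_real_,
      stringsAsFactors = FALSE
    )
    return(list(f_statistic = NA_real_, df = unname(an[["Df"]]),
                p_value = NA_real_, pairwise = pw, pooled_variance = ms_within))
  }
  tk <- stats::TukeyHSD(fit)$group
  pw <- data.frame(
    comparison = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    stringsAsFactors = FALSE
  )
  rownames(pw) <- NULL
  list(
    f_statistic = an["group", "F value"],
    df = unname(an[["Df"]]),
    p_value = an["group", "Pr(>F)"],
    pairwise = pw,
    pooled_variance = ms_within
  )
}

#' Histogram of track displacements
#'
#' Counts over half-open bins `[a, b)`. When a configuration is supplied the
#' non-motile threshold must be one of the bin edges, so that histogram
#' fractions stay consistent with the motility classification.
#'
#' @param metrics A per-track metrics table (or any data frame with a
#'   `net_displacement_um` column).
#' @param bin_edges Strictly increasing numeric vector of bin edges spanning
#'   all observed values (use `Inf` as the last edge for an open tail).
#' @param group Optional group label to restrict to.
#' @param config Optional [analysis_config()] used to enforce the threshold
#'   edge.
#' @return A data frame `bin_lo, bin_hi, count`.
#' @export
displacement_histogram <- function(metrics, bin_edges, group = NULL,
                                   config = NULL) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  if (!is.null(config)) {
    stopifnot(inherits(config, "motility_config"))
    if (!any(abs(bin_edges - config$non_motile_threshold) < 1e-9)) {
      stop("bin_edges must include the non-motile threshold (",
           config$non_motile_threshold, " um) as an edge")
    }
  }
  rows <- if (is.null(group)) metrics else metrics[metrics$group == group, ]
  if (!nrow(rows)) stop("no tracks to bin")
  x <- rows$net_displacement_um
  if (any(x < bin_edges[1] | x >= bin_edges[length(bin_edges)])) {
    stop("displacement values fall outside the bin range")
  }
  # half-open [a, b): a value on an edge belongs to the bin on its right
  idx <- findInterval(x, bin_edges, rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  data.frame(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    count = counts
  )
}
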