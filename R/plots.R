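#' SuperPlot of a per-track metric
#'
#' Cell-level values as jittered points, replicate means as large circles,
#' and the mean of replicate means with an SEM error bar per group — the
#' presentation convention in which the replicate, not the cell, is the
#' statistical unit.
#'
#' @param metrics A metrics table from [track_metrics()].
#' @param metric Metric column to plot (default `"net_displacement_um"`).
#' @return A ggplot object.
#' @export
plot_superplot <- function(metrics, metric = "net_displacement_um") {
  if (!metric %in% names(metrics)) stop("unknown metric: '", metric, "'")
  cells <- data.frame(group = metrics$group, value = metrics[[metric]])
  rm_tab <- replicate_means(metrics, metric)
  gm <- do.call(rbind, lapply(split(rm_tab, rm_tab$group), function(d) {
    data.frame(group = d$group[1], value = mean(d$value),
               sem = if (nrow(d) >= 2) stats::sd(d$value) / sqrt(nrow(d)) else NA_real_)
  }))
  ggplot2::ggplot(cells, ggplot2::aes(x = group, y = value)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.3, size = 0.8, colour = "grey40") +
    ggplot2::geom_point(data = rm_tab, size = 3, shape = 21, fill = "gold") +
    ggplot2::geom_errorbar(
      data = gm,
      ggplot2::aes(ymin = value - sem, ymax = value + sem),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::geom_point(data = gm, shape = 95, size = 8) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_classic()
}

#' Worm plot of tracks
#'
#' Every track translated to a common origin, the standard at-a-glance view
#' of cohort motility.
#'
#' @param cohort A [motility_cohort()].
#' @param max_tracks Cap on the number of tracks drawn (default 100).
#' @return A ggplot object.
#' @export
plot_tracks <- function(cohort, max_tracks = 100) {
  stopifnot(inherits(cohort, "motility_cohort"))
  tl <- cohort_track_list(cohort)
  tl <- tl[seq_len(min(length(tl), max_tracks))]
  df <- do.call(rbind, lapply(names(tl), function(id) {
    p <- tl[[id]]
    data.frame(track_id = id, x = p$x_um - p$x_um[1], y = p$y_um - p$y_um[1])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, group = track_id)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_classic()
}

#' Log-log MSD panel
#'
#' Per-track MSD curves on log-log axes; diffusive tracks appear as lines of
#' slope 1, ballistic rollers as slope 2, tethered cells as a plateau.
#'
#' @param cohort A [motility_cohort()].
#' @param max_tracks Cap on the number of curves drawn (default 100).
#' @return A ggplot object.
#' @export
plot_msd <- function(cohort, max_tracks = 100) {
  msd <- cohort_msd(cohort)
  ids <- unique(msd$track_id)
  msd <- msd[msd$track_id %in% ids[seq_len(min(length(ids), max_tracks))], ]
  msd <- msd[msd$msd_um2 > 0, ]
  names(msd)[names(msd) == "lag_s"] <- "lag"
  names(msd)[names(msd) == "msd_um2"] <- "msd"
  ggplot2::ggplot(msd, ggplot2::aes(x = lag, y = msd, group = track_id)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (s)", y = "MSD (µm²)") +
    ggplot2::theme_classic()
}
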