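as_track_points <- function(track) {
  if (inherits(track, "motility_cohort")) {
    ids <- unique(track$tracks$track_id)
    if (length(ids) != 1L) {
      stop("expected a single track; got a cohort with ", length(ids), " tracks")
    }
    track <- track$tracks
  }
  stopifnot(all(c("t_s", "x_um", "y_um") %in% names(track)))
  track
}

#' Net track displacement
#'
#' Euclidean distance (µm) between a track's first and last observed
#' positions — the "track displacement" reported per cell over the 5-minute
#' observation window. Distinct from the total [path_length()].
#'
#' @param track A single-track data frame with columns `t_s`, `x_um`, `y_um`
#'   (or a one-track [motility_cohort()]).
#' @return Net displacement in µm.
#' @export
net_displacement <- function(track) {
  p <- as_track_points(track)
  n <- nrow(p)
  if (n < 2L) stop("net_displacement requires at least 2 points")
  sqrt((p$x_um[n] - p$x_um[1])^2 + (p$y_um[n] - p$y_um[1])^2)
}

#' Total path length
#'
#' Sum of Euclidean distances between consecutive observed points (µm).
#' Gaps are not interpolated: the segment spanning a gap is the straight
#' line between the two observed points.
#'
#' @inheritParams net_displacement
#' @return Path length in µm.
#' @export
path_length <- function(track) {
  p <- as_track_points(track)
  if (nrow(p) < 2L) stop("path_length requires at least 2 points")
  sum(sqrt(diff(p$x_um)^2 + diff(p$y_um)^2))
}

#' Persistence (confinement) ratio
#'
#' Net displacement divided by total path length: 1 for perfectly straight
#' monotone motion, near 0 for confined or wandering motion. Defined as 0
#' when the path length is 0 (a perfectly stationary track).
#'
#' @inheritParams net_displacement
#' @return A unitless value in `[0, 1]`.
#' @export
persistence_ratio <- function(track) {
  p <- as_track_points(track)
  if (nrow(p) < 2L) stop("persistence_ratio requires at least 2 points")
  pl <- path_length(p)
  if (pl == 0) return(0)
  net_displacement(p) / pl
}

#' All-pairs mean squared displacement
#'
#' For every lag tau = k * `frame_interval` the MSD is the average of the
#' squared displacements between *all* pairs of observed positions separated
#' by tau within the track (not just consecutive windows). With gaps, pairs
#' are formed only between observed points and lags with zero pairs are
#' omitted; the lag grid remains multiples of the frame interval.
#'
#' @inheritParams net_displacement
#' @param frame_interval Frame interval in seconds; inferred from the
#'   smallest time step when `NULL`.
#' @return An `msd_curve`: a data frame with columns `lag_s`, `msd_um2`,
#'   `n_pairs` and attributes `frame_interval` and `duration`.
#' @export
msd_all_pairs <- function(track, frame_interval = NULL) {
  p <- as_track_points(track)
  n <- nrow(p)
  if (n < 2L) stop("msd_all_pairs requires at least 2 points")
  if (is.null(frame_interval)) frame_interval <- min(diff(p$t_s))
  stopifnot(frame_interval > 0)
  frames <- (p$t_s - p$t_s[1]) / frame_interval
  if (any(abs(frames - round(frames)) > 1e-6)) {
    stop("track times are not on a grid of frame_interval = ", frame_interval)
  }
  frames <- as.integer(round(frames))
  max_f <- frames[n]
  # index of the observation at each frame (NA where the frame is missing)
  slot <- rep(NA_integer_, max_f + 1L)
  slot[frames + 1L] <- seq_len(n)
  lags <- integer(0); msd <- numeric(0); n_pairs <- integer(0)
  for (k in seq_len(max_f)) {
    i <- slot[seq_len(max_f + 1L - k)]
    j <- slot[seq_len(max_f + 1L - k) + k]
    ok <- !is.na(i) & !is.na(j)
    if (!any(ok)) next
    d2 <- (p$x_um[j[ok]] - p$x_um[i[ok]])^2 + (p$y_um[j[ok]] - p$y_um[i[ok]])^2
    lags <- c(lags, k); msd <- c(msd, mean(d2)); n_pairs <- c(n_pairs, sum(ok))
  }
  structure(
    data.frame(lag_s = lags * frame_interval, msd_um2 = msd, n_pairs = n_pairs),
    frame_interval = frame_interval,
    duration = p$t_s[n] - p$t_s[1],
    class = c("msd_curve", "data.frame")
  )
}

#' Anomalous-diffusion exponent from an MSD curve
#'
#' Ordinary (unweighted) least-squares slope of `log(msd)` versus `log(lag)`
#' over lags up to `max_lag_fraction` of the track duration — the exponent
#' alpha: about 1 for a random walk, 2 for ballistic motion, below 1 for
#' confined/tethered cells. Zero-MSD lags are dropped (their logarithm is
#' undefined); if fewer than two usable lags remain the slope is undefined
#' and `NA` is returned.
#'
#' @param msd An `msd_curve` from [msd_all_pairs()].
#' @param max_lag_fraction Fraction of track duration limiting fitted lags
#'   (default 0.25).
#' @param duration Track duration in seconds; taken from the curve's
#'   attribute when `NULL`.
#' @return The slope alpha, or `NA_real_` when undefined.
#' @export
fit_alpha <- function(msd, max_lag_fraction = 0.25, duration = NULL) {
  stopifnot(max_lag_fraction > 0, max_lag_fraction <= 1)
  if (!nrow(msd)) stop("empty MSD curve")
  if (is.null(duration)) duration <- attr(msd, "duration")
  if (is.null(duration)) stop("track duration unknown; pass `duration`")
  keep <- msd$lag_s <= max_lag_fraction * duration & msd$msd_um2 > 0
  if (sum(keep) < 2L) return(NA_real_)
  lx <- log(msd$lag_s[keep])
  ly <- log(msd$msd_um2[keep])
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Classify tracks by motility and diffusion regime
#'
#' Motility: `non_motile` when net displacement is below the configured
#' threshold (2 µm by default, the published cutoff); `roller` when both the
#' net displacement and the persistence ratio exceed the roller thresholds
#' (long, straight tracks of detached cells carried by flow); otherwise
#' `motile`. Diffusion regime from the fitted MSD exponent: `subdiffusive`
#' below `alpha_subdiffusive_max`, `superdiffusive` above
#' `alpha_superdiffusive_min`, `diffusive` between, `undefined` when alpha
#' could not be fitted.
#'
#' @param net_displacement,persistence_ratio,alpha Numeric vectors of equal
#'   length (NA alpha allowed).
#' @param config A [analysis_config()].
#' @return A data frame with character columns `motility_class` and
#'   `diffusion_class`.
#' @export
classify_tracks <- function(net_displacement, persistence_ratio, alpha,
                            config = analysis_config()) {
  stopifnot(inherits(config, "motility_config"))
  n <- length(net_displacement)
  stopifnot(length(persistence_ratio) == n, length(alpha) == n)
  motility <- ifelse(
    net_displacement < config$non_motile_threshold, "non_motile",
    ifelse(net_displacement >= config$roller_displacement_min &
             persistence_ratio >= config$roller_persistence_min,
           "roller", "motile")
  )
  diffusion <- ifelse(
    is.na(alpha), "undefined",
    ifelse(alpha < config$alpha_subdiffusive_max, "subdiffusive",
           ifelse(alpha > config$alpha_superdiffusive_min,
                  "superdiffusive", "diffusive"))
  )
  data.frame(motility_class = motility, diffusion_class = diffusion,
             stringsAsFactors = FALSE)
}

#' Per-track metrics table for a cohort
#'
#' Computes, for every track: net displacement, path length, persistence
#' ratio, the all-pairs MSD log-log slope alpha, and the motility/diffusion
#' classes.
#'
#' @param cohort A [motility_cohort()].
#' @param config A [analysis_config()].
#' @return A data frame with one row per track:
#'   `track_id, group, replicate_id, net_displacement_um, path_length_um,
#'   persistence_ratio, alpha, motility_class, diffusion_class`.
#' @export
track_metrics <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "motility_cohort"))
  tl <- cohort_track_list(cohort)
  if (!length(tl)) stop("cohort has no tracks")
  ann <- unique(cohort$tracks[, c("track_id", "group", "replicate_id")])
  rownames(ann) <- NULL
  net <- pl <- pr <- al <- numeric(length(tl))
  for (i in seq_along(tl)) {
    p <- tl[[i]]
    if (nrow(p) < 2L) {
      stop("track '", names(tl)[i], "' has fewer than 2 points; no metric is defined")
    }
    net[i] <- net_displacement(p)
    pl[i] <- path_length(p)
    pr[i] <- persistence_ratio(p)
    msd <- msd_all_pairs(p, frame_interval = cohort$frame_interval)
    al[i] <- fit_alpha(msd, max_lag_fraction = config$msd_max_lag_fraction)
  }
  cls <- classify_tracks(net, pr, al, config)
  out <- data.frame(
    track_id = names(tl),
    stringsAsFactors = FALSE
  )
  out <- merge(out, ann, by = "track_id", sort = FALSE)
  out$net_displacement_um <- net
  out$path_length_um <- pl
  out$persistence_ratio <- pr
  out$alpha <- al
  out$motility_class <- cls$motility_class
  out$diffusion_class <- cls$diffusion_class
  out
}

#' MSD curves for every track in a cohort
#'
#' @param cohort A [motility_cohort()].
#' @return A long data frame `track_id, lag_s, msd_um2, n_pairs`.
#' @export
cohort_msd <- function(cohort) {
  stopifnot(inherits(cohort, "motility_cohort"))
  tl <- cohort_track_list(cohort)
  do.call(rbind, lapply(names(tl), function(id) {
    m <- msd_all_pairs(tl[[id]], frame_interval = cohort$frame_interval)
    cbind(track_id = id, as.data.frame(m), stringsAsFactors = FALSE)
  }))
}

#' Write a per-track metrics table
#'
#' @param metrics A data frame from [track_metrics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
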