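#' Construct a motility cohort
#'
#' A cohort is the central container of the package: a table of timestamped
#' 2-D cell positions (µm) for one or more tracks, each assigned to a
#' biological replicate and an experimental group (strain), sampled on a
#' fixed frame grid. Gaps (missing frames) are allowed and retained; no
#' positions are interpolated.
#'
#' @param tracks A data frame with columns `track_id`, `replicate_id`,
#'   `group`, `t_s`, `x_um`, `y_um`, one row per observed point.
#' @param frame_interval Frame interval in seconds. If `NULL`, inferred as
#'   the smallest positive time step observed in the data.
#' @return An object of class `motility_cohort`: a list with elements
#'   `tracks` (the validated table, ordered by track and time),
#'   `frame_interval`, and `metadata` (the distinct `(group, replicate_id)`
#'   pairs).
#' @export
motility_cohort <- function(tracks, frame_interval = NULL) {
  required <- c("track_id", "replicate_id", "group", "t_s", "x_um", "y_um")
  missing_cols <- setdiff(required, names(tracks))
  if (length(missing_cols)) {
    stop("tracks table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tracks <- as.data.frame(tracks)[, required]
  tracks$track_id <- as.character(tracks$track_id)
  tracks$replicate_id <- as.character(tracks$replicate_id)
  tracks$group <- as.character(tracks$group)
  for (col in c("t_s", "x_um", "y_um")) {
    tracks[[col]] <- as.numeric(tracks[[col]])
  }
  if (nrow(tracks)) {
    if (any(!is.finite(tracks$x_um)) || any(!is.finite(tracks$y_um))) {
      stop("non-finite positions in tracks table")
    }
    if (any(!is.finite(tracks$t_s)) || any(tracks$t_s < 0)) {
      stop("times must be finite and non-negative")
    }
    tracks <- tracks[order(tracks$track_id, tracks$t_s), , drop = FALSE]
    rownames(tracks) <- NULL
    # one (group, replicate) per track; strictly increasing times
    by_id <- split(seq_len(nrow(tracks)), tracks$track_id)
    for (id in names(by_id)) {
      idx <- by_id[[id]]
      if (length(unique(tracks$group[idx])) > 1L ||
          length(unique(tracks$replicate_id[idx])) > 1L) {
        stop("track '", id, "' maps to more than one (group, replicate_id)")
      }
      tt <- tracks$t_s[idx]
      if (any(diff(tt) <= 0)) {
        stop("track '", id, "' has non-increasing or duplicated times")
      }
    }
    if (is.null(frame_interval)) {
      steps <- unlist(lapply(by_id, function(idx) diff(tracks$t_s[idx])),
                      use.names = FALSE)
      if (!length(steps)) stop("cannot infer frame_interval from single-point tracks")
      frame_interval <- min(steps)
    }
    frame_interval <- as.numeric(frame_interval)
    if (frame_interval <= 0) stop("frame_interval must be positive")
    for (id in names(by_id)) {
      steps <- diff(tracks$t_s[by_id[[id]]])
      k <- steps / frame_interval
      if (any(abs(k - round(k)) > 1e-6)) {
        stop("track '", id, "' has point spacing that is not an integer ",
             "multiple of frame_interval = ", frame_interval)
      }
    }
  } else {
    frame_interval <- as.numeric(frame_interval %||% 1)
  }
  metadata <- unique(tracks[, c("group", "replicate_id"), drop = FALSE])
  rownames(metadata) <- NULL
  structure(
    list(tracks = tracks, frame_interval = frame_interval, metadata = metadata),
    class = "motility_cohort"
  )
}

#' @export
print.motility_cohort <- function(x, ...) {
  n_tracks <- length(unique(x$tracks$track_id))
  cat(sprintf(
    "<motility_cohort> %d track(s), %d point(s), frame interval %g s\n",
    n_tracks, nrow(x$tracks), x$frame_interval
  ))
  if (nrow(x$metadata)) {
    tab <- table(x$metadata$group)
    cat("  groups:", paste(sprintf("%s (%d repl.)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Split a cohort into per-track data frames
#'
#' @param cohort A `motility_cohort`.
#' @return A named list of data frames (one per `track_id`, in first-appearance
#'   order) with columns `t_s`, `x_um`, `y_um`.
#' @export
cohort_track_list <- function(cohort) {
  stopifnot(inherits(cohort, "motility_cohort"))
  tr <- cohort$tracks
  ids <- unique(tr$track_id)
  out <- lapply(ids, function(id) {
    d <- tr[tr$track_id == id, c("t_s", "x_um", "y_um"), drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(out) <- ids
  out
}
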