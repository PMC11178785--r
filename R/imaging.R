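#' Render a synthetic movie from a cohort
#'
#' Each cell is drawn as an isotropic Gaussian blob (s.d. = `cell_radius`/2)
#' at its true position in every frame, plus additive Gaussian background
#' noise with s.d. = peak amplitude / `snr`. The µm origin maps to the
#' center of pixel (1, 1) (0-based pixel (0, 0)); rows index y, columns x.
#' Missing frames within a track simply contribute no blob.
#'
#' @param cohort A [motility_cohort()] whose positions all fit inside the
#'   field (simulate with `origins = "grid"`; positions outside the field
#'   raise an error naming the track).
#' @param pixel_size Pixel size in µm/pixel.
#' @param cell_radius Cell radius in µm (default 0.8, half the observed mean
#'   cell diameter of 1.6 µm).
#' @param snr Peak signal-to-noise ratio; `Inf` for noiseless frames.
#' @param field_um Optional `c(width, height)` of the field in µm; computed
#'   from the data plus a margin when `NULL`.
#' @param seed Integer seed for the background noise.
#' @return A `synthetic_movie`: list with `frames` (list of matrices),
#'   `pixel_size`, `frame_interval`, `ground_truth` (data frame
#'   `frame, track_id, x_um, y_um`).
#' @export
render_movie <- function(cohort, pixel_size = 0.2, cell_radius = 0.8,
                         snr = 10, field_um = NULL, seed = 1) {
  stopifnot(inherits(cohort, "motility_cohort"), pixel_size > 0,
            cell_radius > 0, snr > 0)
  tr <- cohort$tracks
  if (!nrow(tr)) stop("cohort has no tracks to render")
  fi <- cohort$frame_interval
  frames_idx <- as.integer(round(tr$t_s / fi))
  n_frames <- max(frames_idx) + 1L
  margin <- 4 * cell_radius
  if (is.null(field_um)) {
    field_um <- c(max(tr$x_um) + margin, max(tr$y_um) + margin)
    if (min(tr$x_um) < margin || min(tr$y_um) < margin) {
      bad <- tr$track_id[tr$x_um < margin | tr$y_um < margin][1]
      stop("track '", bad, "' lies within ", margin,
           " um of the field border; simulate with origins = 'grid' or pass field_um")
    }
  }
  nx <- as.integer(ceiling(field_um[1] / pixel_size)) + 1L
  ny <- as.integer(ceiling(field_um[2] / pixel_size)) + 1L
  outside <- tr$x_um < 0 | tr$y_um < 0 |
    tr$x_um > (nx - 1L) * pixel_size | tr$y_um > (ny - 1L) * pixel_size
  if (any(outside)) {
    stop("positions outside the field for track(s): ",
         paste(unique(tr$track_id[outside]), collapse = ", "))
  }
  s_px <- (cell_radius / 2) / pixel_size
  half_w <- ceiling(4 * s_px)
  noise_sd <- if (is.finite(snr)) 1 / snr else 0
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames) - 1L, function(f) {
      img <- if (noise_sd > 0) {
        matrix(stats::rnorm(ny * nx, 0, noise_sd), nrow = ny, ncol = nx)
      } else {
        matrix(0, nrow = ny, ncol = nx)
      }
      sel <- which(frames_idx == f)
      for (i in sel) {
        cx <- tr$x_um[i] / pixel_size   # 0-based pixel coordinates
        cy <- tr$y_um[i] / pixel_size
        x0 <- max(0L, floor(cx) - half_w); x1 <- min(nx - 1L, ceiling(cx) + half_w)
        y0 <- max(0L, floor(cy) - half_w); y1 <- min(ny - 1L, ceiling(cy) + half_w)
        xs <- x0:x1; ys <- y0:y1
        blob <- exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / (2 * s_px^2))
        img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + blob
      }
      img
    })
  })
  structure(list(
    frames = frames,
    pixel_size = pixel_size,
    frame_interval = fi,
    ground_truth = data.frame(frame = frames_idx, track_id = tr$track_id,
                              x_um = tr$x_um, y_um = tr$y_um,
                              stringsAsFactors = FALSE)
  ), class = "synthetic_movie")
}

#' @export
print.synthetic_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<synthetic_movie> %d frame(s) of %d x %d px (%g um/px, %g s/frame)\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Write / read a synthetic movie as multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` on write (32-bit float TIFF).
#'
#' @param movie A `synthetic_movie`.
#' @param path TIFF file path.
#' @return `write_movie()` returns `path` invisibly; `read_movie_frames()`
#'   returns a list of matrices.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "synthetic_movie"))
  rng <- range(unlist(lapply(movie$frames, range)))
  scale <- if (diff(rng) > 0) diff(rng) else 1
  imgs <- lapply(movie$frames, function(f) (f - rng[1]) / scale)
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie_frames <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(f) if (length(dim(f)) == 3L) f[, , 1L] else f)
}

#' Detect cells in one frame
#'
#' Gaussian smoothing, global thresholding at mean + `threshold_sd` standard
#' deviations of the smoothed frame, connected components of at least
#' `min_area_px` pixels, and an intensity-weighted centroid per component,
#' converted to µm. Touching cells may merge into one component; this
#' detector is deliberately simple and is meant for well-separated blobs.
#'
#' @param frame An intensity matrix (rows = y, columns = x).
#' @param pixel_size Pixel size in µm/pixel.
#' @param threshold_sd Threshold in s.d. units above the mean (default 3).
#' @param min_area_px Minimum component area in pixels (default 4).
#' @param smooth_sigma_px Gaussian smoothing s.d. in pixels (default 2).
#' @return A data frame `x_um, y_um, area_px` (zero rows when nothing is
#'   detected).
#' @export
detect_cells <- function(frame, pixel_size = 0.2, threshold_sd = 3,
                         min_area_px = 4, smooth_sigma_px = 2) {
  stopifnot(is.matrix(frame), all(is.finite(frame)), pixel_size > 0)
  sm <- EBImage::gblur(frame, sigma = smooth_sigma_px)
  thr <- mean(sm) + threshold_sd * stats::sd(sm)
  mask <- sm > thr
  if (!any(mask)) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0), area_px = integer(0)))
  }
  lab <- EBImage::bwlabel(mask)
  labs <- as.integer(lab)
  keep <- which(labs > 0L)
  if (!length(keep)) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0), area_px = integer(0)))
  }
  comp <- labs[keep]
  w <- pmax(frame[keep], 0)
  rows0 <- (keep - 1L) %% nrow(frame)        # 0-based y
  cols0 <- (keep - 1L) %/% nrow(frame)       # 0-based x
  area <- tabulate(comp)
  wsum <- tapply(w, comp, sum)
  cx <- tapply(w * cols0, comp, sum) / wsum
  cy <- tapply(w * rows0, comp, sum) / wsum
  ok <- area[as.integer(names(wsum))] >= min_area_px & wsum > 0
  data.frame(
    x_um = as.numeric(cx[ok]) * pixel_size,
    y_um = as.numeric(cy[ok]) * pixel_size,
    area_px = as.integer(area[as.integer(names(wsum))][ok])
  )
}

#' Detect cells in every frame of a movie
#'
#' @param movie A `synthetic_movie`.
#' @inheritParams detect_cells
#' @return A data frame `frame, x_um, y_um, area_px` (frame is 0-based).
#' @export
detect_movie <- function(movie, threshold_sd = 3, min_area_px = 4,
                         smooth_sigma_px = 2) {
  stopifnot(inherits(movie, "synthetic_movie"))
  out <- lapply(seq_along(movie$frames), function(f) {
    d <- detect_cells(movie$frames[[f]], pixel_size = movie$pixel_size,
                      threshold_sd = threshold_sd, min_area_px = min_area_px,
                      smooth_sigma_px = smooth_sigma_px)
    if (nrow(d)) cbind(frame = f - 1L, d) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_px = integer(0)))
  }
  do.call(rbind, out)
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbor assignment frame to frame: the closest
#' (track, detection) pairs are linked first, links longer than `max_disp`
#' are rejected, each detection joins at most one track, unmatched
#' detections open new tracks, and a track missing for more than `max_gap`
#' consecutive frames is terminated.
#'
#' @param detections A data frame `frame, x_um, y_um` ordered by frame
#'   (0-based frame indices).
#' @param frame_interval Frame interval in seconds.
#' @param max_disp Maximum link displacement in µm per frame step
#'   (default 2, covering the largest twitch step).
#' @param max_gap Maximum bridged gap in frames (default 2).
#' @param group,replicate_id Labels for the output cohort.
#' @return A [motility_cohort()] of recovered tracks (single-point tracks
#'   included; metrics functions reject them explicitly).
#' @export
link_tracks <- function(detections, frame_interval = 1, max_disp = 2,
                        max_gap = 2, group = "recovered", replicate_id = "R1") {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)))
  if (!nrow(detections)) stop("no detections to link")
  det <- detections[order(detections$frame), , drop = FALSE]
  active <- list()   # each: id, x, y, last_frame, rows (list of data.frames)
  closed <- list()
  next_id <- 1L
  for (f in sort(unique(det$frame))) {
    d <- det[det$frame == f, , drop = FALSE]
    # expire tracks whose gap exceeded max_gap
    if (length(active)) {
      last <- vapply(active, function(a) a$last_frame, numeric(1))
      expired <- f - last > max_gap + 1L
      closed <- c(closed, active[expired])
      active <- active[!expired]
    }
    assigned_det <- rep(FALSE, nrow(d))
    if (length(active) && nrow(d)) {
      ax <- vapply(active, function(a) a$x, numeric(1))
      ay <- vapply(active, function(a) a$y, numeric(1))
      dist <- sqrt(outer(ax, d$x_um, "-")^2 + outer(ay, d$y_um, "-")^2)
      assigned_trk <- rep(FALSE, length(active))
      repeat {
        dist_ok <- dist
        dist_ok[assigned_trk, ] <- Inf
        dist_ok[, assigned_det] <- Inf
        m <- which.min(dist_ok)
        if (!length(m) || !is.finite(dist_ok[m]) || dist_ok[m] > max_disp) break
        ti <- (m - 1L) %% length(active) + 1L
        di <- (m - 1L) %/% length(active) + 1L
        a <- active[[ti]]
        a$x <- d$x_um[di]; a$y <- d$y_um[di]; a$last_frame <- f
        a$rows[[length(a$rows) + 1L]] <-
          c(frame = f, x = d$x_um[di], y = d$y_um[di])
        active[[ti]] <- a
        assigned_trk[ti] <- TRUE
        assigned_det[di] <- TRUE
      }
    }
    for (di in which(!assigned_det)) {
      active[[length(active) + 1L]] <- list(
        id = next_id, x = d$x_um[di], y = d$y_um[di], last_frame = f,
        rows = list(c(frame = f, x = d$x_um[di], y = d$y_um[di]))
      )
      next_id <- next_id + 1L
    }
  }
  all_tracks <- c(closed, active)
  rows <- do.call(rbind, lapply(all_tracks, function(a) {
    m <- do.call(rbind, a$rows)
    data.frame(
      track_id = sprintf("L%04d", a$id), replicate_id = replicate_id,
      group = group, t_s = m[, "frame"] * frame_interval,
      x_um = m[, "x"], y_um = m[, "y"], stringsAsFactors = FALSE
    )
  }))
  motility_cohort(rows, frame_interval = frame_interval)
}

#' Match recovered tracks to ground truth
#'
#' For each ground-truth track, finds the recovered track that covers most
#' of its frames within `max_dist`, and reports per-truth-track coverage
#' (fraction of frames matched by that single recovered track).
#'
#' @param recovered A [motility_cohort()] of recovered tracks.
#' @param ground_truth A data frame `frame, track_id, x_um, y_um` (e.g. from
#'   [render_movie()]).
#' @param frame_interval Frame interval in seconds used by the recovery.
#' @param max_dist Maximum match distance in µm (default 1).
#' @return A data frame `truth_id, matched_id, n_frames, n_matched,
#'   coverage`.
#' @export
match_tracks <- function(recovered, ground_truth, frame_interval = 1,
                         max_dist = 1) {
  stopifnot(inherits(recovered, "motility_cohort"))
  rec <- recovered$tracks
  rec$frame <- as.integer(round(rec$t_s / frame_interval))
  out <- lapply(split(ground_truth, ground_truth$track_id), function(g) {
    key <- match(g$frame, rec$frame)
    hits <- character(0)
    for (i in seq_len(nrow(g))) {
      cand <- rec[rec$frame == g$frame[i], , drop = FALSE]
      if (!nrow(cand)) next
      dd <- sqrt((cand$x_um - g$x_um[i])^2 + (cand$y_um - g$y_um[i])^2)
      j <- which.min(dd)
      if (dd[j] <= max_dist) hits <- c(hits, cand$track_id[j])
    }
    best <- if (length(hits)) names(sort(table(hits), decreasing = TRUE))[1] else NA_character_
    n_matched <- if (is.na(best)) 0L else sum(hits == best)
    data.frame(truth_id = g$track_id[1], matched_id = best,
               n_frames = nrow(g), n_matched = n_matched,
               coverage = n_matched / nrow(g), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
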