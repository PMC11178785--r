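#' Simulate one cell track under a phenotype preset
#'
#' Mechanistic agent-based simulation of pilus-retraction-driven twitching.
#' In `twitcher` mode, pili nucleate as a Poisson process at
#' `pilus_nucleation_rate`, each with a uniform random direction and a
#' truncated-normal length; the tip anchors on the surface and the pilus
#' retracts at its own truncated-normal speed. While a single pilus is
#' attached the cell body moves toward its anchor at the retraction speed;
#' with several attached pili it moves toward the equal-weight centroid of
#' the anchors (the cell ends up "in the middle" of the adhered pili) at the
#' mean of the active speeds. When a retraction completes, with probability
#' `recoil_prob` the cell takes one `recoil_step` backward along the pilus
#' axis (backward slip upon loss of surface attachment). `tethered` cells
#' show isotropic Gaussian wobble about a fixed anchor; `roller` cells dwell,
#' then travel at constant velocity in a random fixed direction. Positions
#' are sampled every `frame_interval` with isotropic localization noise.
#'
#' @param preset A [phenotype_preset()].
#' @param mode One of `"twitcher"`, `"tethered"`, `"roller"`.
#' @param seed Integer seed; identical `(preset, mode, seed)` give
#'   bit-identical output.
#' @param origin Numeric length-2 start position in µm (default the origin).
#' @return A list with elements `track` (data frame `t_s`, `x_um`, `y_um`),
#'   `mode`, `events` (per-pilus ground truth: nucleation time, true speed,
#'   length, anchor position) and `anchor` (tether/start point).
#' @export
simulate_track <- function(preset, mode, seed, origin = c(0, 0)) {
  validate_preset(preset)
  if (!mode %in% c("twitcher", "tethered", "roller")) {
    stop("unknown mode: '", mode, "'")
  }
  with_seed(seed, {
    n_frames <- floor(preset$duration / preset$frame_interval) + 1L
    t_s <- (seq_len(n_frames) - 1L) * preset$frame_interval
    res <- switch(mode,
      twitcher = sim_twitcher(preset, n_frames),
      tethered = sim_tethered(preset, n_frames),
      roller   = sim_roller(preset, n_frames)
    )
    noise <- matrix(stats::rnorm(2L * n_frames, 0, preset$localization_noise_sd),
                    ncol = 2L)
    track <- data.frame(
      t_s = t_s,
      x_um = res$xy[, 1L] + noise[, 1L] + origin[1L],
      y_um = res$xy[, 2L] + noise[, 2L] + origin[2L]
    )
    events <- res$events
    if (nrow(events)) {
      events$anchor_x_um <- events$anchor_x_um + origin[1L]
      events$anchor_y_um <- events$anchor_y_um + origin[2L]
    }
    list(track = track, mode = mode, events = events, anchor = origin)
  })
}

empty_event_table <- function() {
  data.frame(t_s = numeric(0), speed_um_per_s = numeric(0),
             length_um = numeric(0), anchor_x_um = numeric(0),
             anchor_y_um = numeric(0))
}

# Twitcher dynamics integrated on a sub-frame grid (10 substeps per frame).
# Pilus state: anchor, nucleation axis, retraction speed, remaining length.
# A pilus detaches when its remaining length reaches zero.
sim_twitcher <- function(preset, n_frames) {
  dt <- preset$frame_interval / 10
  p_nuc <- preset$pilus_nucleation_rate * dt
  xy <- matrix(0, nrow = n_frames, ncol = 2L)
  pos <- c(0, 0)
  ax <- ay <- ux <- uy <- vr <- rem <- numeric(0)
  ev_t <- ev_v <- ev_l <- ev_ax <- ev_ay <- numeric(0)
  for (f in seq_len(n_frames)) {
    xy[f, ] <- pos
    if (f == n_frames) break
    t0 <- (f - 1L) * preset$frame_interval
    for (s in 1:10) {
      # nucleation
      if (length(vr) < preset$multi_pilus_max && stats::runif(1) < p_nuc) {
        theta <- stats::runif(1, 0, 2 * pi)
        len <- rtrunc_norm(1, preset$pilus_length_mean, preset$pilus_length_sd,
                           0, preset$pilus_length_max)
        spd <- rtrunc_norm(1, preset$retraction_speed_mean,
                           preset$retraction_speed_sd,
                           preset$retraction_speed_min, preset$retraction_speed_max)
        ux <- c(ux, cos(theta)); uy <- c(uy, sin(theta))
        ax <- c(ax, pos[1] + len * cos(theta))
        ay <- c(ay, pos[2] + len * sin(theta))
        vr <- c(vr, spd); rem <- c(rem, len)
        ev_t <- c(ev_t, t0 + (s - 1L) * dt)
        ev_v <- c(ev_v, spd); ev_l <- c(ev_l, len)
        ev_ax <- c(ev_ax, pos[1] + len * cos(theta))
        ev_ay <- c(ev_ay, pos[2] + len * sin(theta))
      }
      if (length(vr)) {
        # move toward the equal-weight centroid of the attached anchors
        target <- c(mean(ax), mean(ay))
        delta <- target - pos
        dist <- sqrt(sum(delta^2))
        step <- mean(vr) * dt
        pos <- if (dist <= step) target else pos + delta * (step / dist)
        rem <- rem - vr * dt
        done <- rem <= 1e-12
        if (any(done)) {
          for (j in which(done)) {
            if (preset$recoil_prob > 0 && stats::runif(1) < preset$recoil_prob) {
              pos <- pos - preset$recoil_step * c(ux[j], uy[j])
            }
          }
          keep <- !done
          ax <- ax[keep]; ay <- ay[keep]; ux <- ux[keep]; uy <- uy[keep]
          vr <- vr[keep]; rem <- rem[keep]
        }
      }
    }
  }
  list(xy = xy, events = data.frame(
    t_s = ev_t, speed_um_per_s = ev_v, length_um = ev_l,
    anchor_x_um = ev_ax, anchor_y_um = ev_ay
  ))
}

sim_tethered <- function(preset, n_frames) {
  xy <- matrix(stats::rnorm(2L * n_frames, 0, preset$tether_jitter_sd),
               ncol = 2L)
  list(xy = xy, events = empty_event_table())
}

sim_roller <- function(preset, n_frames) {
  dwell <- stats::runif(1, 0, preset$roller_dwell_max)
  theta <- stats::runif(1, 0, 2 * pi)
  t_s <- (seq_len(n_frames) - 1L) * preset$frame_interval
  travel <- pmax(0, t_s - dwell) * preset$roller_speed
  list(xy = cbind(travel * cos(theta), travel * sin(theta)),
       events = empty_event_table())
}

#' Simulate a cohort of tracks
#'
#' Modes are drawn i.i.d. from the preset's `mode_fractions`; tracks are
#' distributed round-robin over replicates. Per-track random streams are
#' derived from the root seed by a fixed counter scheme, so identical
#' `(preset, n_tracks, n_replicates, seed)` give bit-identical cohorts.
#'
#' @param preset A [phenotype_preset()].
#' @param n_tracks Number of tracks (>= 1).
#' @param n_replicates Number of biological replicates (default 3).
#' @param seed Integer root seed.
#' @param origins `"origin"` (all tracks start at (0, 0); track statistics
#'   are translation invariant) or `"grid"` (tracks start on a square grid —
#'   required before rendering a movie, where cells must not overlap).
#' @param grid_spacing,grid_margin Grid geometry in µm for `origins = "grid"`.
#' @return A list with elements `cohort` (a [motility_cohort()]), `modes`
#'   (data frame `track_id`, `replicate_id`, `group`, `mode` — the per-track
#'   ground truth) and `events` (per-pilus ground truth across all tracks).
#' @export
simulate_cohort <- function(preset, n_tracks, n_replicates = 3, seed = 1,
                            origins = c("origin", "grid"),
                            grid_spacing = 25, grid_margin = 15) {
  validate_preset(preset)
  origins <- match.arg(origins)
  stopifnot(n_tracks >= 1, n_replicates >= 1)
  mode_names <- names(preset$mode_fractions)
  modes <- with_seed(seed, {
    sample(mode_names, n_tracks, replace = TRUE, prob = preset$mode_fractions)
  })
  n_cols <- ceiling(sqrt(n_tracks))
  rows <- vector("list", n_tracks)
  event_rows <- vector("list", n_tracks)
  track_ids <- sprintf("%s_%04d", preset$name, seq_len(n_tracks))
  replicate_ids <- paste0("R", ((seq_len(n_tracks) - 1L) %% n_replicates) + 1L)
  for (i in seq_len(n_tracks)) {
    org <- if (origins == "grid") {
      c(grid_margin + ((i - 1L) %% n_cols) * grid_spacing,
        grid_margin + ((i - 1L) %/% n_cols) * grid_spacing)
    } else c(0, 0)
    sim <- simulate_track(preset, modes[i], derive_seed(seed, i), origin = org)
    rows[[i]] <- data.frame(
      track_id = track_ids[i], replicate_id = replicate_ids[i],
      group = preset$name,
      t_s = sim$track$t_s, x_um = sim$track$x_um, y_um = sim$track$y_um,
      stringsAsFactors = FALSE
    )
    ev <- sim$events
    if (nrow(ev)) {
      ev <- cbind(track_id = track_ids[i], ev, stringsAsFactors = FALSE)
      event_rows[[i]] <- ev
    }
  }
  cohort <- motility_cohort(do.call(rbind, rows),
                            frame_interval = preset$frame_interval)
  events <- if (any(!vapply(event_rows, is.null, logical(1)))) {
    do.call(rbind, event_rows[!vapply(event_rows, is.null, logical(1))])
  } else {
    cbind(track_id = character(0), empty_event_table())
  }
  list(
    cohort = cohort,
    modes = data.frame(track_id = track_ids, replicate_id = replicate_ids,
                       group = preset$name, mode = modes,
                       stringsAsFactors = FALSE),
    events = events
  )
}

#' Simulate a single-pilus retraction trace
#'
#' Pilus length decreases linearly at `true_speed` from `L0` to zero, sampled
#' every `frame_interval` (default 0.5 s, matching the imaging cadence used
#' for pilus dynamics), with additive Gaussian length noise clipped at zero.
#' A few zero-length tail frames are appended after full retraction.
#'
#' @param true_speed True retraction speed in µm/s (> 0).
#' @param L0 Initial pilus length in µm (0 < L0 <= 14).
#' @param noise_sd Gaussian length-noise s.d. in µm (default 0).
#' @param frame_interval Sampling interval in seconds (default 0.5).
#' @param seed Integer seed.
#' @param cell_id,pilus_id Identifiers written into the trace.
#' @param tail_frames Number of post-retraction zero-length frames (default 2).
#' @return A list with `trace` (data frame `cell_id`, `pilus_id`, `t_s`,
#'   `length_um`) and `truth` (list `speed`, `L0`).
#' @export
simulate_retraction_trace <- function(true_speed, L0, noise_sd = 0,
                                      frame_interval = 0.5, seed = 1,
                                      cell_id = "sim_cell", pilus_id = "p1",
                                      tail_frames = 2) {
  if (!is.finite(true_speed) || true_speed <= 0) stop("true_speed must be positive")
  if (!is.finite(L0) || L0 <= 0 || L0 > 14) stop("L0 must lie in (0, 14] um")
  stopifnot(frame_interval > 0, noise_sd >= 0)
  n_retract <- ceiling(L0 / (true_speed * frame_interval))
  t_s <- (0:(n_retract + tail_frames)) * frame_interval
  len <- pmax(L0 - true_speed * t_s, 0)
  trace <- with_seed(seed, {
    noisy <- pmax(len + stats::rnorm(length(len), 0, noise_sd), 0)
    data.frame(cell_id = cell_id, pilus_id = pilus_id,
               t_s = t_s, length_um = noisy, stringsAsFactors = FALSE)
  })
  list(trace = trace, truth = list(speed = true_speed, L0 = L0))
}

#' Simulate unbiased Gaussian-step random-walk tracks
#'
#' Reference diffusive tracks (isotropic Gaussian steps, no drift) used to
#' validate the MSD slope estimator: their per-track log-log MSD slope is 1
#' in expectation.
#'
#' @param n_tracks Number of tracks.
#' @param n_frames Frames per track (default 300).
#' @param step_sd Per-frame step s.d. in µm per coordinate (default 0.25).
#' @param frame_interval Frame interval in seconds (default 1).
#' @param seed Integer root seed.
#' @param group Group label (default `"diffusion"`).
#' @param n_replicates Replicates for round-robin assignment (default 3).
#' @return A [motility_cohort()].
#' @export
simulate_diffusion_cohort <- function(n_tracks, n_frames = 300, step_sd = 0.25,
                                      frame_interval = 1, seed = 1,
                                      group = "diffusion", n_replicates = 3) {
  stopifnot(n_tracks >= 1, n_frames >= 2, step_sd > 0)
  rows <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    xy <- with_seed(derive_seed(seed, i), {
      apply(matrix(stats::rnorm(2L * (n_frames - 1L), 0, step_sd), ncol = 2L),
            2, cumsum)
    })
    rows[[i]] <- data.frame(
      track_id = sprintf("%s_%04d", group, i),
      replicate_id = paste0("R", ((i - 1L) %% n_replicates) + 1L),
      group = group,
      t_s = (seq_len(n_frames) - 1L) * frame_interval,
      x_um = c(0, xy[, 1L]), y_um = c(0, xy[, 2L]),
      stringsAsFactors = FALSE
    )
  }
  motility_cohort(do.call(rbind, rows), frame_interval = frame_interval)
}
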