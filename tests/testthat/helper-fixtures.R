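# Shared fixtures and independent oracles used across the test files.

# Random valid cohort with optional gaps, for round-trip and property tests.
random_cohort <- function(n_tracks, n_points = 10, frame_interval = 1,
                          gap_prob = 0, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_tracks), function(i) {
      keep <- c(TRUE, stats::runif(n_points - 1) >= gap_prob)
      t_s <- ((seq_len(n_points) - 1) * frame_interval)[keep]
      data.frame(
        track_id = sprintf("trk%03d", i),
        replicate_id = paste0("R", (i - 1) %% 3 + 1),
        group = if (i %% 2 == 0) "A" else "B",
        t_s = t_s,
        x_um = round(stats::rnorm(sum(keep), 0, 5), 6),
        y_um = round(stats::rnorm(sum(keep), 0, 5), 6)
      )
    })
    motility_cohort(do.call(rbind, rows), frame_interval = frame_interval)
  })
}

# Brute-force all-pairs MSD: double loop over every ordered pair of points.
msd_oracle <- function(track, frame_interval) {
  n <- nrow(track)
  lag <- numeric(0); d2 <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      lag <- c(lag, track$t_s[j] - track$t_s[i])
      d2 <- c(d2, (track$x_um[j] - track$x_um[i])^2 +
                (track$y_um[j] - track$y_um[i])^2)
    }
  }
  lags <- sort(unique(lag))
  data.frame(
    lag_s = lags,
    msd_um2 = vapply(lags, function(l) mean(d2[lag == l]), numeric(1)),
    n_pairs = vapply(lags, function(l) sum(lag == l), numeric(1))
  )
}

# Minimal TrackMate-style XML: spots with positions, one Track of edges.
write_trackmate_fixture <- function(path, spots, edges) {
  spot_xml <- paste(sprintf(
    '<Spot ID="%d" POSITION_X="%g" POSITION_Y="%g" POSITION_T="%g" />',
    spots$id, spots$x, spots$y, spots$t), collapse = "\n        ")
  edge_xml <- paste(sprintf(
    '<Edge SPOT_SOURCE_ID="%d" SPOT_TARGET_ID="%d" />',
    edges$source, edges$target), collapse = "\n          ")
  writeLines(sprintf('<?xml version="1.0" encoding="UTF-8"?>
<TrackMate version="7.0.0">
  <Model spatialunits="pixel" timeunits="sec">
    <AllSpots nspots="%d">
      <SpotsInFrame frame="0">
        %s
      </SpotsInFrame>
    </AllSpots>
    <AllTracks>
      <Track TRACK_ID="0" NUMBER_SPOTS="%d">
          %s
      </Track>
    </AllTracks>
  </Model>
</TrackMate>', nrow(spots), spot_xml, nrow(spots), edge_xml), path)
  path
}

# One-way ANOVA + Tukey HSD computed from first principles (group means,
# single pooled within-group variance, studentized-range distribution) --
# independent of aov()/TukeyHSD().
tukey_oracle <- function(values, groups) {
  groups <- as.character(groups)
  g <- sort(unique(groups))
  k <- length(g)
  n_i <- vapply(g, function(x) sum(groups == x), numeric(1))
  m_i <- vapply(g, function(x) mean(values[groups == x]), numeric(1))
  grand <- mean(values)
  ss_between <- sum(n_i * (m_i - grand)^2)
  ss_within <- sum((values - m_i[match(groups, g)])^2)
  df1 <- k - 1
  df2 <- length(values) - k
  ms_within <- ss_within / df2
  f_stat <- (ss_between / df1) / ms_within
  combs <- utils::combn(g, 2)
  p_adj <- diff_v <- numeric(ncol(combs))
  lab <- character(ncol(combs))
  for (c_i in seq_len(ncol(combs))) {
    a <- combs[1, c_i]; b <- combs[2, c_i]
    diff_v[c_i] <- m_i[b] - m_i[a]
    se <- sqrt(ms_within / 2 * (1 / n_i[a] + 1 / n_i[b]))
    p_adj[c_i] <- stats::ptukey(abs(diff_v[c_i]) / se, k, df2, lower.tail = FALSE)
    lab[c_i] <- paste(b, a, sep = "-")
  }
  list(f = f_stat, p = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
       pairwise = data.frame(comparison = lab, diff = diff_v, p_adj = p_adj))
}

# Brute-force retraction-event scan on a raw trace (no smoothing): maximal
# strictly-decreasing runs with drop >= min_drop. Valid oracle for noiseless
# fixtures where smoothing cannot change run boundaries' lengths/levels.
retraction_oracle <- function(t_s, length_um, min_drop) {
  d <- diff(length_um)
  events <- list()
  i <- 1
  while (i <= length(d)) {
    if (d[i] < 0) {
      j <- i
      while (j < length(d) && d[j + 1] < 0) j <- j + 1
      if (length_um[i] - length_um[j + 1] >= min_drop) {
        events[[length(events) + 1]] <- data.frame(
          t_ini_s = t_s[i], t_final_s = t_s[j + 1],
          L_ini_um = length_um[i], L_final_um = length_um[j + 1]
        )
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (length(events)) do.call(rbind, events) else NULL
}
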