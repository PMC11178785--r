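#' Write a run manifest
#'
#' A manifest records everything needed to reproduce a pipeline run
#' byte-identically: package version, root seed, the full configuration and
#' preset snapshots, and an MD5 digest of every file the stage wrote.
#'
#' @param outdir Output directory of the stage.
#' @param seed Root seed of the run.
#' @param files Character vector of file paths to digest.
#' @param config Optional [analysis_config()] snapshot.
#' @param preset Optional [phenotype_preset()] snapshot.
#' @param extra Optional named list of additional fields.
#' @return The manifest (a list), invisibly; written to
#'   `file.path(outdir, "manifest.yaml")`.
#' @export
write_manifest <- function(outdir, seed, files, config = NULL, preset = NULL,
                           extra = list()) {
  digests <- as.list(tools::md5sum(files))
  names(digests) <- basename(files)
  manifest <- c(list(
    package = "pilitrack",
    version = as.character(utils::packageVersion("pilitrack")),
    seed = as.integer(seed),
    files = digests
  ), extra)
  if (!is.null(config)) manifest$config <- unclass(config)
  if (!is.null(preset)) {
    p <- unclass(preset)
    p$mode_fractions <- as.list(p$mode_fractions)
    manifest$preset <- p
  }
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

#' Simulate a cohort and write all outputs
#'
#' Runs [simulate_cohort()] for a named or explicit preset and writes the
#' track table, the per-track ground-truth mode table, the per-pilus event
#' table, a set of single-pilus retraction traces drawn from the preset's
#' retraction-speed distribution, a preset snapshot, and a manifest.
#'
#' @param preset A [phenotype_preset()] or the name of a built-in preset.
#' @param n_tracks,n_replicates,seed Passed to [simulate_cohort()].
#' @param outdir Output directory (created if needed).
#' @param n_traces Number of single-pilus retraction traces to generate
#'   (default 19, the published single-pilus sample size).
#' @param trace_noise_sd Length-noise s.d. (µm) for the traces (default 0.05).
#' @param origins Passed to [simulate_cohort()].
#' @return Invisibly, a list with the simulated objects and output paths.
#' @export
run_simulation <- function(preset, n_tracks, n_replicates = 3, seed = 1,
                           outdir, n_traces = 19, trace_noise_sd = 0.05,
                           origins = "origin") {
  if (is.character(preset)) {
    presets <- builtin_presets()
    if (!preset %in% names(presets)) {
      stop("unknown preset '", preset, "'; built-ins: ",
           paste(names(presets), collapse = ", "))
    }
    preset <- presets[[preset]]
  }
  validate_preset(preset)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(preset, n_tracks, n_replicates, seed, origins = origins)
  tracks_path <- file.path(outdir, "tracks.csv")
  write_tracks(sim$cohort, tracks_path)
  truth_path <- file.path(outdir, "ground_truth.csv")
  utils::write.csv(sim$modes, truth_path, row.names = FALSE, quote = FALSE)
  events_path <- file.path(outdir, "pilus_events.csv")
  utils::write.csv(sim$events, events_path, row.names = FALSE, quote = FALSE)

  traces <- do.call(rbind, lapply(seq_len(n_traces), function(i) {
    tr_seed <- derive_seed(seed, 100000L + i)
    draws <- with_seed(tr_seed, list(
      speed = rtrunc_norm(1, preset$retraction_speed_mean,
                          preset$retraction_speed_sd,
                          preset$retraction_speed_min, preset$retraction_speed_max),
      L0 = stats::runif(1, 2, 8)
    ))
    simulate_retraction_trace(draws$speed, draws$L0, noise_sd = trace_noise_sd,
                              seed = derive_seed(seed, 200000L + i),
                              cell_id = sprintf("cell_%03d", i))$trace
  }))
  traces_path <- file.path(outdir, "pilus_traces.csv")
  write_pilus_traces(traces, traces_path)
  preset_path <- file.path(outdir, "preset.yaml")
  write_presets(preset, preset_path)
  write_manifest(outdir, seed,
                 c(tracks_path, truth_path, events_path, traces_path, preset_path),
                 preset = preset,
                 extra = list(n_tracks = n_tracks, n_replicates = n_replicates))
  invisible(list(sim = sim, traces = traces, outdir = outdir,
                 files = c(tracks = tracks_path, ground_truth = truth_path,
                           events = events_path, traces = traces_path)))
}

#' Analyze a track table (and optionally pilus traces)
#'
#' Reads a track table, computes per-track metrics and MSD curves, group
#' summaries for displacement / persistence / alpha, the displacement
#' histogram, and — when at least two groups have two or more replicates —
#' the replicate-mean ANOVA with Tukey comparisons. When a pilus-trace file
#' is given, retraction events, the replicate-aware mean speed and the
#' speed-length correlation are computed as well; when it is absent those
#' outputs are skipped with a message.
#'
#' @param tracks_path Path to a track table.
#' @param outdir Output directory.
#' @param traces_path Optional path to a pilus-trace table.
#' @param config A [analysis_config()].
#' @return Invisibly, a list with all computed tables.
#' @export
run_analysis <- function(tracks_path, outdir, traces_path = NULL,
                         config = analysis_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cohort <- read_tracks(tracks_path)
  metrics <- track_metrics(cohort, config)
  write_track_metrics(metrics, file.path(outdir, "track_metrics.csv"))
  msd <- cohort_msd(cohort)
  utils::write.csv(msd, file.path(outdir, "msd_curves.csv"),
                   row.names = FALSE, quote = FALSE)
  summaries <- do.call(rbind, lapply(
    c("net_displacement_um", "persistence_ratio", "alpha"),
    function(m) summarize_cohort(metrics, m, config)
  ))
  utils::write.csv(summaries, file.path(outdir, "group_summaries.csv"),
                   row.names = FALSE, quote = FALSE)
  hist_edges <- c(seq(0, max(
    config$non_motile_threshold,
    ceiling(max(metrics$net_displacement_um) / 2) * 2
  ), by = config$non_motile_threshold), Inf)
  hist_tab <- displacement_histogram(metrics, hist_edges, config = config)
  utils::write.csv(hist_tab, file.path(outdir, "displacement_histogram.csv"),
                   row.names = FALSE, quote = FALSE)
  rm_tab <- replicate_means(metrics)
  eligible <- table(rm_tab$group) >= 2
  tukey <- NULL
  if (sum(eligible) >= 2) {
    rm_ok <- rm_tab[rm_tab$group %in% names(eligible)[eligible], ]
    tukey <- anova_tukey(rm_ok)
    utils::write.csv(tukey$pairwise, file.path(outdir, "tukey_pairwise.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    message("fewer than 2 groups with >= 2 replicates; ANOVA skipped")
  }
  retr <- NULL
  if (!is.null(traces_path) && file.exists(traces_path)) {
    traces <- read_pilus_traces(traces_path, max_length = config$pilus_length_max)
    events <- detect_all_retractions(traces,
                                     min_drop = config$retraction_min_drop,
                                     smoothing_window = config$retraction_smoothing_window)
    write_retraction_events(events, file.path(outdir, "retraction_events.csv"))
    retr <- list(events = events)
    if (nrow(events) >= 3) {
      retr$speed_length <- speed_length_relation(events,
                                                 method = config$speed_length_method)
    }
  } else if (!is.null(traces_path)) {
    warning("pilus trace file not found; retraction outputs skipped")
  }
  files <- list.files(outdir, full.names = TRUE, pattern = "\\.csv$")
  write_manifest(outdir, config$rng_seed, files, config = config)
  invisible(list(cohort = cohort, metrics = metrics, summaries = summaries,
                 histogram = hist_tab, tukey = tukey, retraction = retr))
}

#' Render a cohort, re-detect and re-link it, and report recovery
#'
#' End-to-end validation stage: renders the cohort to a synthetic movie,
#' detects cells per frame, links detections into tracks, writes the movie
#' (TIFF), the recovered track table and a ground-truth matching report.
#'
#' @param cohort A [motility_cohort()] (positions must fit the field; use
#'   `simulate_cohort(..., origins = "grid")`).
#' @param outdir Output directory.
#' @param pixel_size,cell_radius,snr,seed Passed to [render_movie()].
#' @param max_disp,max_gap Passed to [link_tracks()].
#' @param write_tiff Write the rendered movie to disk (default TRUE).
#' @return Invisibly, a list with the movie, detections, recovered cohort
#'   and the matching report.
#' @export
run_render_and_track <- function(cohort, outdir, pixel_size = 0.2,
                                 cell_radius = 0.8, snr = 10, seed = 1,
                                 max_disp = 2, max_gap = 2,
                                 write_tiff = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  movie <- render_movie(cohort, pixel_size = pixel_size,
                        cell_radius = cell_radius, snr = snr, seed = seed)
  if (write_tiff) write_movie(movie, file.path(outdir, "movie.tif"))
  detections <- detect_movie(movie)
  recovered <- link_tracks(detections, frame_interval = movie$frame_interval,
                           max_disp = max_disp, max_gap = max_gap)
  write_tracks(recovered, file.path(outdir, "recovered_tracks.csv"))
  report <- match_tracks(recovered, movie$ground_truth,
                         frame_interval = movie$frame_interval,
                         max_dist = cell_radius)
  utils::write.csv(report, file.path(outdir, "matching_report.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(outdir, seed,
                 file.path(outdir, c("recovered_tracks.csv", "matching_report.csv")),
                 extra = list(pixel_size = pixel_size, snr = snr,
                              max_disp = max_disp, max_gap = max_gap))
  invisible(list(movie = movie, detections = detections,
                 recovered = recovered, report = report))
}
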