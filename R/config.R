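#' Analysis configuration
#'
#' Bundles every numeric threshold used by the track-statistics pipeline so
#' that each one is traceable in outputs and manifests.
#'
#' @param non_motile_threshold Net displacement (µm) below which a track is
#'   classified non-motile. Default 2 µm, the cutoff used for the published
#'   cohorts (roughly one cell diameter over the 5-minute observation window).
#' @param msd_max_lag_fraction Fraction of the track duration up to which MSD
#'   lags enter the log-log slope fit (default 0.25; long lags have few
#'   displacement pairs and high variance).
#' @param alpha_subdiffusive_max Tracks with fitted MSD slope below this value
#'   are called subdiffusive (default 0.5).
#' @param alpha_superdiffusive_min Tracks with slope above this value are
#'   called superdiffusive (default 1.2, the upper edge of the slope cluster
#'   observed for wild-type twitching).
#' @param roller_persistence_min,roller_displacement_min A track is classified
#'   as a roller (detached cell carried by convection flow) when its
#'   persistence ratio and net displacement both exceed these values
#'   (defaults 0.5 and 10 µm).
#' @param retraction_min_drop Minimum total length drop (µm) for a detected
#'   pilus-retraction event (default 0.5).
#' @param retraction_smoothing_window Odd moving-average window (frames) used
#'   before retraction-event detection (default 3).
#' @param speed_length_method Correlation used to relate retraction speed and
#'   initial pilus length: `"pearson"` (default) or `"spearman"`.
#' @param pilus_length_max Maximum admissible pilus length (µm) in traces
#'   (default 14).
#' @param rng_seed Root seed recorded in manifests and used by pipeline
#'   drivers (default 1).
#'
#' @return An object of class `motility_config` (a named list).
#' @export
analysis_config <- function(non_motile_threshold = 2,
                            msd_max_lag_fraction = 0.25,
                            alpha_subdiffusive_max = 0.5,
                            alpha_superdiffusive_min = 1.2,
                            roller_persistence_min = 0.5,
                            roller_displacement_min = 10,
                            retraction_min_drop = 0.5,
                            retraction_smoothing_window = 3,
                            speed_length_method = c("pearson", "spearman"),
                            pilus_length_max = 14,
                            rng_seed = 1L) {
  speed_length_method <- match.arg(speed_length_method)
  cfg <- list(
    non_motile_threshold = as.numeric(non_motile_threshold),
    msd_max_lag_fraction = as.numeric(msd_max_lag_fraction),
    alpha_subdiffusive_max = as.numeric(alpha_subdiffusive_max),
    alpha_superdiffusive_min = as.numeric(alpha_superdiffusive_min),
    roller_persistence_min = as.numeric(roller_persistence_min),
    roller_displacement_min = as.numeric(roller_displacement_min),
    retraction_min_drop = as.numeric(retraction_min_drop),
    retraction_smoothing_window = as.integer(retraction_smoothing_window),
    speed_length_method = speed_length_method,
    pilus_length_max = as.numeric(pilus_length_max),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "motility_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$msd_max_lag_fraction > 0, cfg$msd_max_lag_fraction <= 1,
    cfg$non_motile_threshold > 0,
    cfg$roller_persistence_min > 0, cfg$roller_displacement_min > 0,
    cfg$retraction_min_drop > 0,
    cfg$retraction_smoothing_window >= 1,
    cfg$pilus_length_max > 0
  )
  if (cfg$alpha_subdiffusive_max >= cfg$alpha_superdiffusive_min) {
    stop("alpha_subdiffusive_max must be below alpha_superdiffusive_min")
  }
  invisible(cfg)
}

#' Read / write an analysis configuration as YAML
#'
#' The file is a flat key-value mapping mirroring the [analysis_config()]
#' fields; missing keys take the defaults.
#'
#' @param path File path.
#' @return `read_analysis_config()` returns a `motility_config`;
#'   `write_analysis_config()` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @rdname read_analysis_config
#' @param config A `motility_config`.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "motility_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.motility_config <- function(x, ...) {
  cat("<motility_config>\n")
  for (k in names(x)) cat(sprintf("  %-28s %s\n", k, format(x[[k]])))
  invisible(x)
}
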