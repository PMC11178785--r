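#' Phenotype presets for the twitching simulator
#'
#' A preset bundles every parameter of the mechanistic simulator for one
#' strain-like behavior. Cells come in three modes: *twitchers* perform a
#' saltatory walk driven by pilus nucleation/retraction cycles, *tethered*
#' cells wobble isotropically about a fixed point, and *rollers* detach and
#' travel in a near-straight line with the convection flow.
#'
#' @param name Preset label, also used as the simulated group name.
#' @param mode_fractions Named probabilities over
#'   `c(twitcher=, tethered=, roller=)`; must sum to 1.
#' @param pilus_nucleation_rate Pilus nucleation rate (events/s) per twitcher.
#'   Not measured in live imaging; a free calibration parameter (see the
#'   methods vignette).
#' @param pilus_length_mean,pilus_length_sd,pilus_length_max Truncated-normal
#'   parameters (µm) of nucleated pilus lengths, on `(0, pilus_length_max]`.
#'   The observed fibers reach about 14 µm, the default maximum.
#' @param retraction_speed_mean,retraction_speed_sd Truncated-normal
#'   parameters (µm/s) of per-pilus retraction speed.
#' @param retraction_speed_min,retraction_speed_max Support of the retraction
#'   speed distribution; must lie within the observed 0.3–2 µm/s range.
#' @param multi_pilus_max Maximum number of simultaneously attached pili.
#' @param recoil_step Backward-slip step (µm) taken with probability
#'   `recoil_prob` when a retraction completes (loss of surface attachment).
#' @param recoil_prob Probability of a backward slip per completed retraction.
#' @param tether_jitter_sd Isotropic wobble s.d. (µm) of tethered cells.
#' @param roller_speed Roller travel speed (µm/s).
#' @param roller_dwell_max Rollers dwell in place for a uniform random time in
#'   `[0, roller_dwell_max]` seconds before detaching.
#' @param localization_noise_sd Isotropic localization noise s.d. (µm) added
#'   to every sampled position.
#' @param duration Track duration in seconds (default 300 = 5 min).
#' @param frame_interval Sampling interval in seconds (default 1).
#'
#' @return An object of class `phenotype_preset`.
#' @seealso [builtin_presets()] for the calibrated per-strain defaults.
#' @export
phenotype_preset <- function(name,
                             mode_fractions = c(twitcher = 1, tethered = 0, roller = 0),
                             pilus_nucleation_rate = 0.08,
                             pilus_length_mean = 1.5,
                             pilus_length_sd = 0.5,
                             pilus_length_max = 14,
                             retraction_speed_mean = 0.3,
                             retraction_speed_sd = 0.15,
                             retraction_speed_min = 0.3,
                             retraction_speed_max = 2,
                             multi_pilus_max = 3,
                             recoil_step = 0.3,
                             recoil_prob = 0.3,
                             tether_jitter_sd = 0.15,
                             roller_speed = 0.3,
                             roller_dwell_max = 60,
                             localization_noise_sd = 0.03,
                             duration = 300,
                             frame_interval = 1) {
  modes <- c("twitcher", "tethered", "roller")
  mf <- mode_fractions
  if (is.null(names(mf)) && length(mf) == 3L) names(mf) <- modes
  if (!setequal(names(mf), modes)) {
    stop("mode_fractions must be named over {twitcher, tethered, roller}")
  }
  mf <- as.numeric(mf[modes])
  names(mf) <- modes
  if (any(mf < 0 | mf > 1) || abs(sum(mf) - 1) > 1e-9) {
    stop("mode_fractions must lie in [0, 1] and sum to 1")
  }
  preset <- structure(list(
    name = as.character(name),
    mode_fractions = mf,
    pilus_nucleation_rate = as.numeric(pilus_nucleation_rate),
    pilus_length_mean = as.numeric(pilus_length_mean),
    pilus_length_sd = as.numeric(pilus_length_sd),
    pilus_length_max = as.numeric(pilus_length_max),
    retraction_speed_mean = as.numeric(retraction_speed_mean),
    retraction_speed_sd = as.numeric(retraction_speed_sd),
    retraction_speed_min = as.numeric(retraction_speed_min),
    retraction_speed_max = as.numeric(retraction_speed_max),
    multi_pilus_max = as.integer(multi_pilus_max),
    recoil_step = as.numeric(recoil_step),
    recoil_prob = as.numeric(recoil_prob),
    tether_jitter_sd = as.numeric(tether_jitter_sd),
    roller_speed = as.numeric(roller_speed),
    roller_dwell_max = as.numeric(roller_dwell_max),
    localization_noise_sd = as.numeric(localization_noise_sd),
    duration = as.numeric(duration),
    frame_interval = as.numeric(frame_interval)
  ), class = "phenotype_preset")
  validate_preset(preset)
}

validate_preset <- function(p) {
  stopifnot(inherits(p, "phenotype_preset"))
  mf <- p$mode_fractions
  if (any(mf < 0 | mf > 1) || abs(sum(mf) - 1) > 1e-9) {
    stop("mode_fractions must lie in [0, 1] and sum to 1")
  }
  positive <- c("pilus_nucleation_rate", "pilus_length_mean",
                "pilus_length_max", "retraction_speed_mean",
                "roller_speed", "duration", "frame_interval")
  for (f in positive) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) stop("preset field '", f, "' must be positive")
  }
  nonneg <- c("pilus_length_sd", "retraction_speed_sd", "recoil_step",
              "recoil_prob", "tether_jitter_sd", "roller_dwell_max",
              "localization_noise_sd")
  for (f in nonneg) {
    if (!is.finite(p[[f]]) || p[[f]] < 0) stop("preset field '", f, "' must be non-negative")
  }
  if (p$recoil_prob > 1) stop("recoil_prob must be at most 1")
  if (p$multi_pilus_max < 1) stop("multi_pilus_max must be at least 1")
  # observed retraction speeds span 0.3-2 um/s; the sampled support must stay inside
  if (p$retraction_speed_min < 0.3 - 1e-12 || p$retraction_speed_max > 2 + 1e-12 ||
      p$retraction_speed_min >= p$retraction_speed_max) {
    stop("retraction speed support must lie within [0.3, 2] um/s")
  }
  invisible(p)
}

#' @export
print.phenotype_preset <- function(x, ...) {
  cat(sprintf("<phenotype_preset> %s\n", x$name))
  mf <- x$mode_fractions
  cat(sprintf("  modes: twitcher %.3f / tethered %.3f / roller %.3f\n",
              mf["twitcher"], mf["tethered"], mf["roller"]))
  cat(sprintf("  pili: rate %.4g /s, length %.3g +/- %.3g (max %g) um, speed %.3g +/- %.3g um/s\n",
              x$pilus_nucleation_rate, x$pilus_length_mean, x$pilus_length_sd,
              x$pilus_length_max, x$retraction_speed_mean, x$retraction_speed_sd))
  cat(sprintf("  duration %g s at %g s/frame, noise sd %g um\n",
              x$duration, x$frame_interval, x$localization_noise_sd))
  invisible(x)
}

#' Calibrated built-in strain presets
#'
#' Returns the frozen, packaged presets calibrated so that simulated cohorts
#' reproduce the published cohort statistics: `WT` (motile twitchers with a
#' small tethered fraction), `daapF` (adhesion-pilin deletion; immobile or
#' barely-motile cells), `darlJ` (archaellum deletion; WT-like motility with
#' almost no tethered cells) and `daapB` (pilus-assembly deletion; tethered
#' cells plus a detached roller fraction producing long straight tracks).
#' Parameter values are read verbatim from the packaged preset file
#' (`inst/extdata/presets.yaml`); pilus nucleation rates and per-cell pilus
#' counts are free calibration parameters, not measured quantities.
#'
#' @return A named list of [phenotype_preset()] objects.
#' @export
builtin_presets <- function() {
  path <- system.file("extdata", "presets.yaml", package = "pilitrack")
  if (!nzchar(path)) stop("packaged preset file not found")
  read_presets(path)
}

#' Read / write phenotype presets as YAML
#'
#' The file maps preset names to flat key-value fields mirroring
#' [phenotype_preset()].
#'
#' @param path File path.
#' @return `read_presets()` returns a named list of presets;
#'   `write_presets()` returns `path` invisibly.
#' @export
read_presets <- function(path) {
  if (!file.exists(path)) stop("preset file not found: ", path)
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    fields <- raw[[nm]]
    fields$mode_fractions <- unlist(fields$mode_fractions)
    do.call(phenotype_preset, c(list(name = nm), fields))
  })
  stats::setNames(out, names(raw))
}

#' @rdname read_presets
#' @param presets A named list of `phenotype_preset` objects (or a single one).
#' @export
write_presets <- function(presets, path) {
  if (inherits(presets, "phenotype_preset")) {
    presets <- stats::setNames(list(presets), presets$name)
  }
  out <- lapply(presets, function(p) {
    validate_preset(p)
    fields <- unclass(p)
    fields$name <- NULL
    fields$mode_fractions <- as.list(fields$mode_fractions)
    fields
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
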