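#' Detect pilus-retraction events in a length trace
#'
#' The trace is smoothed with a centered moving average (partial windows at
#' the ends), and maximal runs of strictly decreasing smoothed length are
#' taken as candidate events; plateaus split runs, so two drops separated by
#' a constant stretch yield two events. Event boundaries are then read from
#' the *unsmoothed* trace: the end point is the first sample attaining the
#' run's minimum length and the start point is the last sample attaining the
#' run's maximum before it (this trims the one-sample spill-over that
#' smoothing introduces at plateau edges). Runs whose total unsmoothed drop
#' is below `min_drop` are discarded.
#'
#' @param trace A single-pilus trace: data frame with columns `cell_id`,
#'   `pilus_id`, `t_s`, `length_um` (one `(cell_id, pilus_id)` only).
#' @param min_drop Minimum total length drop in µm (default 0.5).
#' @param smoothing_window Odd moving-average window in frames (default 3).
#' @return A `retraction_events` data frame with columns `cell_id`,
#'   `pilus_id`, `t_ini_s`, `t_final_s`, `L_ini_um`, `L_final_um`,
#'   `speed_um_per_s`; zero rows when no event qualifies. Events are ordered
#'   and never overlap in time.
#' @export
detect_retractions <- function(trace, min_drop = 0.5, smoothing_window = 3) {
  stopifnot(all(c("cell_id", "pilus_id", "t_s", "length_um") %in% names(trace)))
  if (nrow(unique(trace[, c("cell_id", "pilus_id")])) != 1L) {
    stop("detect_retractions expects a single (cell_id, pilus_id) trace; ",
         "loop over traces or use detect_all_retractions()")
  }
  if (nrow(trace) < 3L) stop("trace too short: at least 3 samples required")
  if (any(diff(trace$t_s) <= 0)) stop("trace times must be strictly increasing")
  L <- trace$length_um
  t <- trace$t_s
  sm <- moving_average(L, smoothing_window)
  dec <- diff(sm) < -1e-12
  runs <- rle(dec)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (r in which(runs$values)) {
    # diffs starts[r]..ends[r] decreasing -> samples starts[r]..ends[r]+1
    idx <- starts[r]:(ends[r] + 1L)
    seg <- L[idx]
    i_min <- idx[which.min(seg)]
    pre <- idx[idx <= i_min]
    i_max <- max(pre[L[pre] == max(L[pre])])
    if (i_max >= i_min) next
    drop <- L[i_max] - L[i_min]
    if (drop < min_drop) next
    out[[length(out) + 1L]] <- data.frame(
      cell_id = trace$cell_id[1], pilus_id = trace$pilus_id[1],
      t_ini_s = t[i_max], t_final_s = t[i_min],
      L_ini_um = L[i_max], L_final_um = L[i_min],
      speed_um_per_s = drop / (t[i_min] - t[i_max]),
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    cell_id = character(0), pilus_id = character(0),
    t_ini_s = numeric(0), t_final_s = numeric(0),
    L_ini_um = numeric(0), L_final_um = numeric(0),
    speed_um_per_s = numeric(0), stringsAsFactors = FALSE
  )
  structure(res, class = c("retraction_events", "data.frame"))
}

#' @rdname detect_retractions
#' @param traces A pilus-trace table covering any number of
#'   `(cell_id, pilus_id)` pairs.
#' @export
detect_all_retractions <- function(traces, min_drop = 0.5, smoothing_window = 3) {
  traces <- validate_pilus_traces(traces, max_length = Inf)
  key <- paste(traces$cell_id, traces$pilus_id, sep = "\r")
  parts <- split(traces, key)
  res <- do.call(rbind, lapply(parts, function(tr) {
    as.data.frame(detect_retractions(tr, min_drop = min_drop,
                                     smoothing_window = smoothing_window))
  }))
  rownames(res) <- NULL
  structure(res, class = c("retraction_events", "data.frame"))
}

#' Retraction speed of detected events
#'
#' The speed of a retraction event is the length change over the elapsed
#' time, `(L_ini - L_final) / (t_final - t_ini)`, reported as a positive
#' magnitude (the raw final-minus-initial difference is negative for a
#' retraction).
#'
#' @param events A `retraction_events` data frame (or any data frame with
#'   `L_ini_um`, `L_final_um`, `t_ini_s`, `t_final_s`).
#' @return Numeric vector of speeds in µm/s.
#' @export
retraction_speed <- function(events) {
  stopifnot(all(c("L_ini_um", "L_final_um", "t_ini_s", "t_final_s") %in% names(events)))
  dt <- events$t_final_s - events$t_ini_s
  if (any(dt <= 0)) stop("retraction event with non-positive duration")
  dl <- events$L_ini_um - events$L_final_um
  if (any(dl < 0)) stop("retraction event with increasing length")
  abs(dl) / dt
}

#' Relation between retraction speed and initial pilus length
#'
#' Correlation (Pearson by default, Spearman optionally) between event speed
#' and initial length, with a two-sided p-value — the check that retraction
#' speed does not depend on how long the pilus was.
#'
#' @param events A `retraction_events` data frame with at least 3 events.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list with `estimate` (correlation), `p_value`, `n`, `method`,
#'   and `degenerate` (`TRUE`, with `NA` estimate and a warning, when either
#'   variable has zero variance).
#' @export
speed_length_relation <- function(events, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- nrow(events)
  if (n < 3L) stop("at least 3 events are required, got ", n)
  speed <- retraction_speed(events)
  len <- events$L_ini_um
  if (stats::sd(speed) == 0 || stats::sd(len) == 0) {
    warning("zero variance in speed or initial length; correlation undefined")
    return(list(estimate = NA_real_, p_value = NA_real_, n = n,
                method = method, degenerate = TRUE))
  }
  ct <- stats::cor.test(len, speed, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = n,
       method = method, degenerate = FALSE)
}

#' Replicate-aware mean retraction speed
#'
#' SuperPlot convention: the statistical unit is the biological replicate.
#' Event speeds are first averaged within each replicate; the grand mean and
#' the SEM are then taken across the replicate means. With a single
#' replicate the mean is defined but the SEM is `NA` and flagged.
#'
#' @param events A `retraction_events` data frame.
#' @param replicate_id Character vector assigning each event to a replicate
#'   (recycled from an `events$replicate_id` column when present).
#' @return A list with `grand_mean`, `replicate_means` (named), `sem`
#'   (`NA` when fewer than 2 replicates), `n_replicates`, `n_events`,
#'   and `sem_defined`.
#' @export
mean_retraction_speed <- function(events, replicate_id = events$replicate_id) {
  if (!nrow(events)) stop("no retraction events supplied")
  if (is.null(replicate_id)) {
    stop("replicate assignment required: pass `replicate_id` or include an ",
         "events$replicate_id column")
  }
  stopifnot(length(replicate_id) == nrow(events))
  speed <- retraction_speed(events)
  rep_means <- c(tapply(speed, as.character(replicate_id), mean))
  n_rep <- length(rep_means)
  sem <- if (n_rep >= 2L) stats::sd(rep_means) / sqrt(n_rep) else NA_real_
  list(
    grand_mean = mean(rep_means),
    replicate_means = rep_means,
    sem = sem,
    n_replicates = n_rep,
    n_events = nrow(events),
    sem_defined = n_rep >= 2L
  )
}

#' Write a retraction-events table
#'
#' @param events A `retraction_events` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_retraction_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
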