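#' Read cell tracks from a table or TrackMate XML
#'
#' Two sources are supported: the package's delimited track-table format
#' (header `track_id,replicate_id,group,t_s,x_um,y_um`) and the spot/edge
#' subset of a TrackMate XML model. All positions are carried internally in
#' micrometres; when the source stores pixels, supply `pixel_size` and the
#' conversion happens once, here at the boundary.
#'
#' @param path Path to the input file.
#' @param format `"table"` (default) or `"trackmate_xml"`.
#' @param pixel_size Pixel size in µm/pixel, applied multiplicatively to the
#'   source coordinates. `NULL` (default) means the source is already in µm.
#'   TrackMate files do not record the camera pixel size, so it must be given
#'   explicitly when needed.
#' @param frame_interval Frame interval in seconds; inferred from the data
#'   when `NULL`.
#' @param group,replicate_id Labels assigned to TrackMate-imported tracks
#'   (the XML carries neither concept).
#' @return A [motility_cohort()].
#' @export
read_tracks <- function(path, format = c("table", "trackmate_xml"),
                        pixel_size = NULL, frame_interval = NULL,
                        group = "ungrouped", replicate_id = "R1") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "table") {
    read_track_table(path, pixel_size = pixel_size, frame_interval = frame_interval)
  } else {
    read_trackmate_xml(path, pixel_size = pixel_size, frame_interval = frame_interval,
                       group = group, replicate_id = replicate_id)
  }
}

read_track_table <- function(path, pixel_size = NULL, frame_interval = NULL) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  expected <- c("track_id", "replicate_id", "group", "t_s", "x_um", "y_um")
  if (!identical(trimws(header), expected)) {
    stop("track table header must be '", paste(expected, collapse = ","),
         "', got '", paste(header, collapse = ","), "'")
  }
  df <- utils::read.csv(path, colClasses = c(
    track_id = "character", replicate_id = "character", group = "character",
    t_s = "character", x_um = "character", y_um = "character"
  ))
  for (col in c("t_s", "x_um", "y_um")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad) || anyNA(vals)) {
      line <- (if (length(bad)) bad[1] else which(is.na(vals))[1]) + 1L
      stop("malformed value in column '", col, "' at line ", line, " of ", path)
    }
    df[[col]] <- vals
  }
  # duplicated (track_id, t) caught here with the offending track named
  key <- paste(df$track_id, df$t_s)
  if (anyDuplicated(key)) {
    stop("duplicated (track_id, t_s) in track '",
         df$track_id[duplicated(key)][1], "'")
  }
  if (!is.null(pixel_size)) {
    stopifnot(pixel_size > 0)
    df$x_um <- df$x_um * pixel_size
    df$y_um <- df$y_um * pixel_size
  }
  motility_cohort(df, frame_interval = frame_interval)
}

# Read-only subset of the TrackMate model: Model/AllSpots spot records
# (POSITION_X/POSITION_Y/POSITION_T) and Model/AllTracks edge records
# (SPOT_SOURCE_ID/SPOT_TARGET_ID). Feature tables are ignored; all track
# features are recomputed by this package.
read_trackmate_xml <- function(path, pixel_size = NULL, frame_interval = NULL,
                               group = "ungrouped", replicate_id = "R1") {
  doc <- xml2::read_xml(path)
  spots <- xml2::xml_find_all(doc, ".//Model/AllSpots//Spot")
  if (!length(spots)) stop("no Spot elements found in ", path)
  spot_attr <- function(nodes, attr) {
    v <- xml2::xml_attr(nodes, attr)
    if (anyNA(v)) {
      stop("Spot element ", which(is.na(v))[1], " lacks attribute '", attr, "' in ", path)
    }
    v
  }
  spot_id <- spot_attr(spots, "ID")
  sx <- as.numeric(spot_attr(spots, "POSITION_X"))
  sy <- as.numeric(spot_attr(spots, "POSITION_Y"))
  st <- as.numeric(spot_attr(spots, "POSITION_T"))
  if (anyNA(sx) || anyNA(sy) || anyNA(st)) stop("non-numeric spot position in ", path)
  idx_of <- stats::setNames(seq_along(spot_id), spot_id)

  track_nodes <- xml2::xml_find_all(doc, ".//Model/AllTracks/Track")
  if (!length(track_nodes)) stop("no Track elements found in ", path)
  rows <- list()
  for (tn in seq_along(track_nodes)) {
    node <- track_nodes[[tn]]
    tid <- xml2::xml_attr(node, "TRACK_ID")
    if (is.na(tid)) tid <- as.character(tn)
    edges <- xml2::xml_find_all(node, "./Edge")
    if (!length(edges)) next
    src <- xml2::xml_attr(edges, "SPOT_SOURCE_ID")
    tgt <- xml2::xml_attr(edges, "SPOT_TARGET_ID")
    ids <- unique(c(src, tgt))
    unknown <- ids[!ids %in% names(idx_of)]
    if (length(unknown)) {
      stop("edge in track ", tid, " references unknown spot ID ", unknown[1])
    }
    sel <- idx_of[ids]
    ord <- order(st[sel])
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = paste0("TM", tid),
      replicate_id = replicate_id,
      group = group,
      t_s = st[sel][ord],
      x_um = sx[sel][ord],
      y_um = sy[sel][ord],
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no tracks with edges found in ", path)
  df <- do.call(rbind, rows)
  if (!is.null(pixel_size)) {
    stopifnot(pixel_size > 0)
    df$x_um <- df$x_um * pixel_size
    df$y_um <- df$y_um * pixel_size
  }
  motility_cohort(df, frame_interval = frame_interval)
}

#' Write a cohort to the track-table format
#'
#' Values are written with full `%.17g` precision so that
#' `read_tracks(write_tracks(c))` reproduces `c` exactly.
#'
#' @param cohort A [motility_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(cohort, path) {
  stopifnot(inherits(cohort, "motility_cohort"))
  df <- cohort$tracks
  lines <- c(
    "track_id,replicate_id,group,t_s,x_um,y_um",
    if (nrow(df)) sprintf("%s,%s,%s,%.17g,%.17g,%.17g",
                          df$track_id, df$replicate_id, df$group,
                          df$t_s, df$x_um, df$y_um)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read / write pilus-length traces
#'
#' Pilus traces are tables with header `cell_id,pilus_id,t_s,length_um`, one
#' row per sample of the length (µm) of one pilus over time. Lengths must be
#' non-negative, not exceed `max_length` (the longest fibers observed are
#' about 14 µm), and times must be strictly increasing within each
#' `(cell_id, pilus_id)`.
#'
#' @param path File path.
#' @param max_length Maximum admissible pilus length in µm (default 14).
#' @return `read_pilus_traces()` returns the validated data frame;
#'   `write_pilus_traces()` returns `path` invisibly.
#' @export
read_pilus_traces <- function(path, max_length = 14) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  expected <- c("cell_id", "pilus_id", "t_s", "length_um")
  if (!identical(trimws(header), expected)) {
    stop("pilus trace header must be '", paste(expected, collapse = ","), "'")
  }
  df <- utils::read.csv(path, colClasses = c(
    cell_id = "character", pilus_id = "character",
    t_s = "numeric", length_um = "numeric"
  ))
  validate_pilus_traces(df, max_length = max_length)
}

#' @rdname read_pilus_traces
#' @param traces A pilus-trace data frame.
#' @export
write_pilus_traces <- function(traces, path) {
  traces <- validate_pilus_traces(traces)
  lines <- c(
    "cell_id,pilus_id,t_s,length_um",
    if (nrow(traces)) sprintf("%s,%s,%.17g,%.17g",
                              traces$cell_id, traces$pilus_id,
                              traces$t_s, traces$length_um)
  )
  writeLines(lines, path)
  invisible(path)
}

validate_pilus_traces <- function(df, max_length = 14) {
  required <- c("cell_id", "pilus_id", "t_s", "length_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("pilus trace table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, required]
  df$cell_id <- as.character(df$cell_id)
  df$pilus_id <- as.character(df$pilus_id)
  if (any(!is.finite(df$length_um)) || any(df$length_um < 0)) {
    stop("pilus lengths must be finite and non-negative")
  }
  if (any(df$length_um > max_length)) {
    stop("pilus length exceeds the configured maximum of ", max_length, " um")
  }
  key <- paste(df$cell_id, df$pilus_id)
  df <- df[order(key, df$t_s), , drop = FALSE]
  rownames(df) <- NULL
  for (k in unique(key)) {
    tt <- df$t_s[paste(df$cell_id, df$pilus_id) == k]
    if (any(diff(tt) <= 0)) stop("non-increasing times in pilus trace '", k, "'")
  }
  df
}
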