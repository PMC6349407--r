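#' Assemble a tracked-cell population
#'
#' A population bundles the long-format track table of all cells followed in
#' one or more time-lapse datasets with the acquisition metadata the
#' downstream analysis needs: the (uniform) frame interval `dt` and the
#' x-coordinate of the ventral midline. All positions are physical
#' coordinates in micrometres and times are in hours; angles produced later
#' are referenced to the midline axis.
#'
#' @param tracks Data frame with columns `cell_id`, `frame` (0-based integer),
#'   `x_um`, `y_um`, `z_um`, and optionally `t_hr`, `side` (`"left"` or
#'   `"right"` of the midline), `condition` and `slice_id`. Missing optional
#'   columns are filled (`t_hr` from `frame * dt`; `side` from each cell's
#'   mean x relative to `midline_x`).
#' @param dt Frame interval in hours (e.g. `1/6` for 10-min sampling).
#' @param midline_x x-coordinate of the midline in micrometres.
#' @param provenance Optional free-form metadata (e.g. source file path).
#'
#' @return An object of class `population`: a list with elements `tracks`
#'   (tibble), `dt`, `midline_x`, `n_frames` and `provenance`.
#' @export
#' @examples
#' tr <- tibble::tibble(
#'   cell_id = rep(c("a", "b"), each = 3), frame = rep(0:2, 2),
#'   x_um = c(0, 1, 2, 5, 5, 5), y_um = 0, z_um = 0
#' )
#' population(tr, dt = 1 / 6, midline_x = -10)
population <- function(tracks, dt, midline_x, provenance = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number (hours).")
  }
  if (!is.numeric(midline_x) || length(midline_x) != 1L || !is.finite(midline_x)) {
    abort("`midline_x` must be a single finite number (micrometres).")
  }
  tracks <- as_tibble(tracks)
  required <- c("cell_id", "frame", "x_um", "y_um", "z_um")
  missing_cols <- setdiff(required, names(tracks))
  if (length(missing_cols) > 0) {
    abort(paste0("`tracks` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tracks$cell_id <- as.character(tracks$cell_id)
  tracks$frame <- as.integer(tracks$frame)
  if (nrow(tracks) > 0) {
    coords <- as.matrix(tracks[, c("x_um", "y_um", "z_um")])
    if (!all(is.finite(coords))) {
      bad <- tracks$cell_id[!stats::complete.cases(coords) |
                              rowSums(!is.finite(coords)) > 0][1]
      abort(paste0("Non-finite coordinates for cell '", bad, "'."))
    }
    if (any(tracks$frame < 0L)) abort("Frame indices must be >= 0.")
  }
  if (!"t_hr" %in% names(tracks)) tracks$t_hr <- tracks$frame * dt
  if (!"condition" %in% names(tracks)) tracks$condition <- "unspecified"
  if (!"slice_id" %in% names(tracks)) tracks$slice_id <- "slice1"
  if (!"side" %in% names(tracks)) {
    mx <- tapply(tracks$x_um, tracks$cell_id, mean)
    tracks$side <- ifelse(as.numeric(mx[tracks$cell_id]) >= midline_x,
                          "right", "left")
  }
  if (nrow(tracks) > 0) {
    if (!all(tracks$side %in% c("left", "right"))) {
      abort("`side` must be 'left' or 'right'.")
    }
    # side must agree with the cell's mean position relative to the midline
    mx <- tapply(tracks$x_um, tracks$cell_id, mean)
    side1 <- tapply(tracks$side, tracks$cell_id, function(s) s[[1]])
    expected <- ifelse(mx >= midline_x, "right", "left")
    off <- names(mx)[side1 != expected]
    if (length(off) > 0) {
      abort(paste0("`side` inconsistent with mean x relative to the midline ",
                   "for cell(s): ", paste(head(off, 5), collapse = ", ")))
    }
    # uniform spacing of recorded times
    terr <- abs(tracks$t_hr - tracks$frame * dt)
    if (any(terr > 1e-6)) {
      bad <- tracks$cell_id[which.max(terr)]
      abort(paste0("Non-uniform frame times (cell '", bad,
                   "'): `t_hr` must equal `frame * dt`."))
    }
  }
  tracks <- tracks[order(tracks$cell_id, tracks$frame), TRACK_COLS]
  structure(
    list(
      tracks = tracks,
      dt = dt,
      midline_x = midline_x,
      n_frames = if (nrow(tracks) > 0) max(tracks$frame) + 1L else 0L,
      provenance = provenance
    ),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  cat("<population> ", length(unique(x$tracks$cell_id)), " cells, ",
      x$n_frames, " frames, dt = ", signif(x$dt, 4), " hr, midline_x = ",
      x$midline_x, " um\n", sep = "")
  invisible(x)
}

#' Read cell tracks from a file
#'
#' Ingests either the package's canonical delimited table (comma-separated,
#' UTF-8, header `cell_id, frame, t_hr, x_um, y_um, z_um, side, condition,
#' slice_id`) or a TrackMate XML export (spots + edges). TrackMate positions
#' are taken as calibrated physical coordinates (micrometres), never pixel
#' indices, so anisotropic voxel sizes are already accounted for by the
#' exporting software.
#'
#' For delimited tables, `dt` and `midline_x` may instead live in a JSON
#' sidecar `<path>.json` (fields `dt`, `midline_x`) written by
#' [write_tracks()]. The midline position is slice metadata that cannot be
#' recovered from the tracks themselves and must be supplied one way or the
#' other.
#'
#' @param path Path to the input file.
#' @param format `"delimited_table"` or `"trackmate_xml"`.
#' @param dt Frame interval in hours. For delimited tables it is inferred
#'   from `t_hr` when present; an explicit value must agree with the file.
#' @param midline_x Midline x-coordinate in micrometres.
#' @param condition,slice_id Labels applied when the file carries none.
#' @return A [population()].
#' @export
read_tracks <- function(path,
                        format = c("delimited_table", "trackmate_xml"),
                        dt = NULL, midline_x = NULL,
                        condition = NULL, slice_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "delimited_table") {
    read_tracks_delim(path, dt, midline_x, condition, slice_id)
  } else {
    read_tracks_trackmate(path, dt, midline_x, condition, slice_id)
  }
}

read_tracks_delim <- function(path, dt, midline_x, condition, slice_id) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(dt)) dt <- meta$dt
  if (is.null(midline_x)) midline_x <- meta$midline_x

  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort(paste0("Parse error in '", path, "' at row ", prob$row[1],
                 ", column ", prob$col[1], ": expected ", prob$expected[1]))
  }
  required <- c("cell_id", "frame", "x_um", "y_um", "z_um")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("'", path, "' is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(dt)) {
    if (!"t_hr" %in% names(tab) || nrow(tab) < 2) {
      abort("`dt` not given and no `t_hr` column to infer it from.")
    }
    steps <- unlist(tapply(tab$t_hr[order(tab$cell_id, tab$frame)],
                           tab$cell_id[order(tab$cell_id, tab$frame)], diff))
    steps <- steps[is.finite(steps)]
    if (length(steps) == 0) abort("Cannot infer `dt`: no consecutive frames.")
    dt <- stats::median(steps)
    if (any(abs(steps - dt) > 1e-6)) {
      abort("Non-uniform frame spacing in `t_hr`; tracks must be uniformly sampled.")
    }
  }
  if (is.null(midline_x)) {
    abort("`midline_x` must be supplied (argument or JSON sidecar); it is slice metadata.")
  }
  if (!is.null(condition)) tab$condition <- condition
  if (!is.null(slice_id)) tab$slice_id <- slice_id
  population(tab, dt = dt, midline_x = as.numeric(midline_x),
             provenance = path)
}

read_tracks_trackmate <- function(path, dt, midline_x, condition, slice_id) {
  if (is.null(midline_x)) abort("`midline_x` must be supplied for TrackMate XML.")
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste0("Malformed XML in '", path,
                                                   "': ", conditionMessage(e))))
  spots <- xml2::xml_find_all(doc, ".//AllSpots/SpotsInFrame/Spot")
  if (length(spots) == 0) abort(paste0("No spots found in '", path, "'."))
  num_attr <- function(nodes, attr) {
    v <- suppressWarnings(as.numeric(xml2::xml_attr(nodes, attr)))
    if (anyNA(v)) {
      id <- xml2::xml_attr(nodes, "ID")[which(is.na(v))[1]]
      abort(paste0("Spot '", id, "' has a missing or non-numeric '", attr,
                   "' attribute."))
    }
    v
  }
  spot_tab <- tibble(
    spot_id = xml2::xml_attr(spots, "ID"),
    frame = as.integer(num_attr(spots, "FRAME")),
    x_um = num_attr(spots, "POSITION_X"),
    y_um = num_attr(spots, "POSITION_Y"),
    z_um = num_attr(spots, "POSITION_Z"),
    t = num_attr(spots, "POSITION_T")
  )
  if (is.null(dt)) {
    # POSITION_T is assumed to be in hours already; otherwise pass dt.
    tt <- sort(unique(spot_tab$t))
    if (length(tt) < 2) abort("`dt` not given and cannot be inferred.")
    dt <- stats::median(diff(tt))
  }
  track_nodes <- xml2::xml_find_all(doc, ".//AllTracks/Track")
  if (length(track_nodes) == 0) abort(paste0("No tracks found in '", path, "'."))
  rows <- lapply(track_nodes, function(tn) {
    tid <- xml2::xml_attr(tn, "TRACK_ID")
    edges <- xml2::xml_find_all(tn, "./Edge")
    ids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                    xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    sub <- spot_tab[spot_tab$spot_id %in% ids, ]
    if (nrow(sub) == 0) {
      abort(paste0("Track '", tid, "' references no known spots."))
    }
    sub <- sub[order(sub$frame), ]
    sub$cell_id <- paste0("track_", tid)
    sub
  })
  tab <- dplyr::bind_rows(rows)
  tab$frame <- tab$frame - min(tab$frame)
  tab$t_hr <- tab$frame * dt
  tab <- tab[, c("cell_id", "frame", "t_hr", "x_um", "y_um", "z_um")]
  if (!is.null(condition)) tab$condition <- condition
  if (!is.null(slice_id)) tab$slice_id <- slice_id
  population(tab, dt = dt, midline_x = midline_x, provenance = path)
}

#' Write a population to the canonical delimited format
#'
#' Writes the track table as a comma-separated UTF-8 file and the population
#' metadata (`dt`, `midline_x`, `n_frames`) as a JSON sidecar at
#' `<path>.json`, such that `read_tracks(path)` reproduces the population
#' exactly.
#'
#' @param pop A [population()].
#' @param path Output file path for the delimited table.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(pop, path) {
  stopifnot(inherits(pop, "population"))
  readr::write_csv(pop$tracks, path, progress = FALSE)
  jsonlite::write_json(
    list(dt = pop$dt, midline_x = pop$midline_x, n_frames = pop$n_frames),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Check that every cell is present at every frame
#'
#' Cells whose soma was not detected at all time points of imaging are
#' flagged. The default policy excludes them from further analysis; a single
#' interior gap can instead be filled by linear interpolation between the
#' neighbouring frames (`gaps = "interpolate"`). Leading or trailing gaps
#' cannot be interpolated and always lead to exclusion under that policy.
#'
#' @param pop A [population()].
#' @param gaps Gap policy: `"exclude"` (default), `"interpolate"`, or
#'   `"keep"` (report only, leave tracks untouched).
#' @return A list with `population` (with the policy applied) and `report`
#'   (tibble with `cell_id`, `n_present`, `missing_frames` — a
#'   comma-separated string — and `flagged`).
#' @export
validate_population <- function(pop, gaps = c("exclude", "interpolate", "keep")) {
  stopifnot(inherits(pop, "population"))
  gaps <- match.arg(gaps)
  nf <- pop$n_frames
  all_frames <- seq_len(nf) - 1L
  by_cell <- split(pop$tracks, pop$tracks$cell_id)
  report <- dplyr::bind_rows(lapply(by_cell, function(d) {
    miss <- setdiff(all_frames, d$frame)
    tibble(
      cell_id = d$cell_id[1],
      n_present = nrow(d),
      missing_frames = paste(miss, collapse = ","),
      flagged = length(miss) > 0
    )
  }))
  if (nrow(report) == 0) {
    report <- tibble(cell_id = character(), n_present = integer(),
                     missing_frames = character(), flagged = logical())
  }
  out_tracks <- pop$tracks
  if (gaps == "exclude") {
    keep <- report$cell_id[!report$flagged]
    out_tracks <- pop$tracks[pop$tracks$cell_id %in% keep, ]
  } else if (gaps == "interpolate") {
    filled <- lapply(by_cell, function(d) {
      miss <- setdiff(all_frames, d$frame)
      if (length(miss) == 0) return(d)
      # interior gaps only: need flanking observations on both sides
      if (min(d$frame) != 0L || max(d$frame) != nf - 1L) return(NULL)
      out <- tibble(
        cell_id = d$cell_id[1], frame = all_frames,
        t_hr = all_frames * pop$dt,
        x_um = approx(d$frame, d$x_um, xout = all_frames)$y,
        y_um = approx(d$frame, d$y_um, xout = all_frames)$y,
        z_um = approx(d$frame, d$z_um, xout = all_frames)$y,
        side = d$side[1], condition = d$condition[1], slice_id = d$slice_id[1]
      )
      out
    })
    out_tracks <- dplyr::bind_rows(filled[!vapply(filled, is.null, logical(1))])
  }
  list(
    population = population(out_tracks, dt = pop$dt, midline_x = pop$midline_x,
                            provenance = pop$provenance),
    report = report
  )
}

#' Extract one cell's position matrix
#'
#' @param pop A [population()].
#' @param cell_id Cell identifier.
#' @return Numeric matrix with columns `x_um`, `y_um`, `z_um`, one row per
#'   frame in frame order.
#' @export
track_positions <- function(pop, cell_id) {
  d <- pop$tracks[pop$tracks$cell_id == cell_id, ]
  if (nrow(d) == 0) abort(paste0("No such cell: '", cell_id, "'"))
  as.matrix(d[order(d$frame), c("x_um", "y_um", "z_um")])
}
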