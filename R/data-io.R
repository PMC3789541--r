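#' One replicate trajectory: measured area over time
#'
#' A `well_series` holds one (time, area) trajectory for a well, tagged with
#' a `source_label` distinguishing imaging positions, modalities or image
#' analysis algorithms when several files are loaded for the same well.
#'
#' @param well Well address, e.g. `"A1"`.
#' @param source_label Free-text label for the data source.
#' @param time Strictly increasing nonnegative times.
#' @param area Positive areas, same length as `time` (>= 2 points).
#' @return An object of class `well_series`.
#' @export
well_series <- function(well, source_label, time, area) {
  well <- toupper(trimws(well))
  parse_well(well) # syntax check
  time <- as.numeric(time)
  area <- as.numeric(area)
  if (length(time) != length(area))
    cm_stop("'time' and 'area' must have equal length", "cm_format_error")
  if (length(time) < 2L)
    cm_stop("a series needs at least 2 points", "cm_format_error")
  if (any(!is.finite(time)) || any(!is.finite(area)))
    cm_stop("non-finite time or area value", "cm_format_error")
  if (any(time < 0))
    cm_stop("time values must be nonnegative", "cm_format_error")
  if (any(diff(time) <= 0))
    cm_stop("time values must be strictly increasing (no duplicates)",
            "cm_format_error")
  if (any(area <= 0))
    cm_stop("area values must be positive", "cm_format_error")
  structure(list(well = well, source_label = as.character(source_label),
                 time = time, area = area),
            class = "well_series")
}

#' Read a per-well tab-separated time/area file
#'
#' Parses the generic two-column text format produced downstream of image
#' processing: one tab-separated row per time point, first column time,
#' second column area. One optional header row (the first row, if any of its
#' fields is non-numeric) is skipped. Rows may arrive out of order and are
#' sorted by time; duplicate times, non-numeric cells, nonpositive areas and
#' files with fewer than two data rows are format errors reported with their
#' line number. The decimal separator is `"."`; a `","` inside a number is
#' rejected rather than locale-guessed. CRLF line endings and trailing blank
#' lines are tolerated.
#'
#' @param path Path to the file (or a connection readable by `readLines`).
#' @param well Well address the file belongs to.
#' @param source_label Label for this file (default `"series1"`).
#' @return A [well_series()].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("time\tarea", "0\t200", "1\t180", "2\t160"), f)
#' ts <- read_well_file(f, "A1")
#' ts$area
#' @export
read_well_file <- function(path, well, source_label = "series1") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^[ \t]*$", lines)
  rows <- which(keep)
  if (!length(rows))
    cm_stop("file contains no data rows", "cm_format_error")

  parse_row <- function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L)
      cm_stop(sprintf("line %d: expected two tab-separated columns", i),
              "cm_format_error")
    if (any(grepl(",", fields[1:2], fixed = TRUE)))
      cm_stop(sprintf(
        "line %d: ',' found in a numeric field (decimal separator must be '.')",
        i), "cm_format_error")
    suppressWarnings(as.numeric(fields[1:2]))
  }

  first <- parse_row(rows[1L])
  if (anyNA(first)) rows <- rows[-1L] # header row
  if (length(rows) < 2L)
    cm_stop("fewer than 2 data rows", "cm_format_error")

  vals <- matrix(NA_real_, nrow = length(rows), ncol = 2L)
  for (k in seq_along(rows)) {
    v <- parse_row(rows[k])
    if (anyNA(v))
      cm_stop(sprintf("line %d: non-numeric data cell", rows[k]),
              "cm_format_error")
    vals[k, ] <- v
  }
  ord <- order(vals[, 1L])
  time <- vals[ord, 1L]
  area <- vals[ord, 2L]
  if (anyDuplicated(time))
    cm_stop("duplicate time values in well file", "cm_format_error")
  well_series(well, source_label, time, area)
}

#' An experiment with its measured trajectories
#'
#' Binds an [experiment()] to the list of [well_series()] loaded for it.
#' Every series must belong to a well assigned to some condition; several
#' series per well (distinct `source_label`s) are allowed.
#'
#' @param exp An [experiment()].
#' @param series List of [well_series()] (may start empty; use
#'   [attach_series()]).
#' @return Object of class `loaded_experiment` with fields `experiment` and
#'   `series`.
#' @export
loaded_experiment <- function(exp, series = list()) {
  validate_experiment(exp)
  loaded <- structure(list(experiment = exp, series = list()),
                      class = "loaded_experiment")
  for (ts in series) loaded <- attach_series(loaded, ts)
  loaded
}

series_key <- function(ts) paste(ts$well, ts$source_label, sep = ":")

#' Attach one trajectory to a loaded experiment
#'
#' @param loaded A [loaded_experiment()].
#' @param ts A [well_series()]; its well must be assigned to a condition and
#'   the (well, source_label) pair must be new.
#' @return The updated `loaded_experiment`.
#' @export
attach_series <- function(loaded, ts) {
  stopifnot(inherits(loaded, "loaded_experiment"), inherits(ts, "well_series"))
  owner <- assigned_wells(loaded$experiment)
  if (!ts$well %in% names(owner))
    cm_stop(sprintf("well %s is not assigned to any condition", ts$well),
            "cm_assignment_error")
  key <- series_key(ts)
  if (key %in% names(loaded$series))
    cm_stop(sprintf("a series labeled '%s' already exists for well %s",
                    ts$source_label, ts$well), "cm_conflict_error")
  loaded$series[[key]] <- ts
  loaded
}

#' @export
print.loaded_experiment <- function(x, ...) {
  print(x$experiment)
  cat(sprintf("  %d series over %d well(s)\n", length(x$series),
              length(unique(vapply(x$series, `[[`, "", "well")))))
  invisible(x)
}

# deterministic series ordering: plate row-major by well, then label
order_series <- function(series) {
  if (!length(series)) return(series)
  wells <- vapply(series, `[[`, "", "well")
  labels <- vapply(series, `[[`, "", "source_label")
  addr <- parse_well(wells)
  series[order(addr$row, addr$column, labels)]
}

#' Export a full experiment (set-up plus data) as one XML document
#'
#' Embeds the set-up template and, per series, the well, source label and
#' every (time, area) point at 17 significant digits, so that
#' [import_experiment_xml()] reproduces each value exactly and downstream
#' analysis of the re-import equals analysis of the original. Every assigned
#' well must carry at least one series.
#'
#' @param loaded A [loaded_experiment()].
#' @param path Optional output file.
#' @return An `xml2::xml_document` (invisibly if `path` is given).
#' @export
export_experiment_xml <- function(loaded, path = NULL) {
  stopifnot(inherits(loaded, "loaded_experiment"))
  validate_experiment(loaded$experiment)
  with_data <- unique(vapply(loaded$series, `[[`, "", "well"))
  missing <- setdiff(names(assigned_wells(loaded$experiment)), with_data)
  if (length(missing))
    cm_stop(sprintf("assigned well(s) with no data series: %s",
                    paste(sort(missing), collapse = ", ")),
            "cm_validation_error")
  doc <- xml2::xml_new_root("experiment")
  add_setup_nodes(doc, loaded$experiment)
  dnode <- xml2::xml_add_child(doc, "data")
  for (ts in order_series(loaded$series)) {
    snode <- xml2::xml_add_child(dnode, "series", well = ts$well,
                                 source_label = ts$source_label)
    for (i in seq_along(ts$time))
      xml2::xml_add_child(snode, "point", time = num17(ts$time[i]),
                          area = num17(ts$area[i]))
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Import a full experiment from XML
#'
#' Inverse of [export_experiment_xml()]: validates the document against the
#' shipped schema, rebuilds the experiment and every series. A series
#' referring to a well not assigned to any condition is a validation error.
#'
#' @param x Path, XML string or `xml2::xml_document`.
#' @return A [loaded_experiment()].
#' @export
import_experiment_xml <- function(x) {
  doc <- read_experiment_doc(x)
  exp <- parse_setup(doc)
  loaded <- loaded_experiment(exp)
  for (snode in xml2::xml_find_all(xml2::xml_root(doc), "./data/series")) {
    pts <- xml2::xml_find_all(snode, "./point")
    ts <- well_series(xml2::xml_attr(snode, "well"),
                      attr_or(snode, "source_label", "series1"),
                      as.numeric(xml2::xml_attr(pts, "time")),
                      as.numeric(xml2::xml_attr(pts, "area")))
    loaded <- attach_series(loaded, ts)
  }
  loaded
}
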