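#' Normalize a trajectory relative to its area at time zero
#'
#' Expresses every area as a percentage of the area at the first time point,
#' so `normalized[1] == 100` exactly, and computes the per-step changes
#' `deltas[i] = normalized[i+1] - normalized[i]` used by quality control.
#' The raw series is retained untouched; normalization is scale-invariant
#' (multiplying all areas by a constant changes nothing).
#'
#' @param ts A [well_series()] with `area[1] > 0`.
#' @return An object of class `normalized_series` with fields `well`,
#'   `source_label`, `time`, `normalized` (percent of t0 area), `deltas`
#'   (length `n - 1`) and the original `series`.
#' @examples
#' ts <- well_series("A1", "pos1", 0:2, c(200, 180, 160))
#' ns <- normalize_series(ts)
#' ns$normalized # 100 90 80
#' ns$deltas     # -10 -10
#' @export
normalize_series <- function(ts) {
  stopifnot(inherits(ts, "well_series"))
  if (ts$area[1L] <= 0)
    cm_stop("area at time 0 must be positive", "cm_value_error")
  normalized <- 100 * ts$area / ts$area[1L]
  structure(list(well = ts$well, source_label = ts$source_label,
                 time = ts$time, normalized = normalized,
                 deltas = diff(normalized), series = ts,
                 assay_kind = NULL, expected_trend = NULL,
                 against_trend = NULL,
                 corrected_steps = integer(), original = NULL),
            class = "normalized_series")
}

#' Annotate the expected migration trend of a normalized series
#'
#' Migration shrinks the cell-free region in an open-area (wound-healing or
#' exclusion-zone) assay and grows the measured region in a covered-area
#' read-out. `orient_series()` records which trend is expected and marks
#' each per-step delta that runs against it (e.g. an area increase in an
#' open-area assay) -- the direction half of the artifact criterion used by
#' [detect_step_artifacts()]. No values are changed or sign-flipped, so
#' fitted slopes stay physically interpretable in both assay kinds.
#'
#' @param ns A [normalize_series()] result.
#' @param assay_kind `"open_area"` (expected trend decreasing) or
#'   `"covered_area"` (expected trend increasing).
#' @return The series with `assay_kind`, `expected_trend` and the logical
#'   vector `against_trend` (one flag per delta) filled in.
#' @export
orient_series <- function(ns, assay_kind = c("open_area", "covered_area")) {
  stopifnot(inherits(ns, "normalized_series"))
  assay_kind <- match.arg(assay_kind)
  ns$assay_kind <- assay_kind
  ns$expected_trend <- if (assay_kind == "open_area") "decreasing" else "increasing"
  ns$against_trend <- if (assay_kind == "open_area") ns$deltas > 0 else ns$deltas < 0
  ns
}

# refresh deltas / against_trend after a correction edits the trajectory
refresh_deltas <- function(ns) {
  ns$deltas <- diff(ns$normalized)
  if (!is.null(ns$assay_kind))
    ns$against_trend <- if (ns$assay_kind == "open_area") ns$deltas > 0 else ns$deltas < 0
  ns
}

#' @export
print.normalized_series <- function(x, ...) {
  cat(sprintf("<normalized_series> %s [%s], %d points", x$well,
              x$source_label, length(x$time)))
  if (!is.null(x$assay_kind))
    cat(sprintf(", %s (expected %s)", x$assay_kind, x$expected_trend))
  cat("\n")
  invisible(x)
}
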