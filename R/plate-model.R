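#' Define a multi-well plate format
#'
#' A plate format fixes the geometry of the experiment: `rows` x `columns`
#' wells. Rows are lettered A..Z (so at most 26 rows), columns are numbered
#' from 1, following the universal microtiter convention.
#'
#' @param rows Number of rows (1--26).
#' @param columns Number of columns (>= 1).
#' @param label Free-text label, e.g. `"96-well"`; defaults to
#'   `"<capacity>-well"`.
#' @return An object of class `plate_format` with fields `rows`, `columns`,
#'   `label`.
#' @examples
#' p <- plate_format(8, 12)
#' plate_capacity(p) # 96
#' @export
plate_format <- function(rows, columns, label = NULL) {
  rows <- check_count(rows, "rows")
  columns <- check_count(columns, "columns")
  if (rows > 26L)
    cm_stop("plates with more than 26 rows (A-Z) are not supported",
            "cm_validation_error")
  if (is.null(label)) label <- sprintf("%d-well", rows * columns)
  structure(list(rows = rows, columns = columns, label = as.character(label)),
            class = "plate_format")
}

#' @rdname plate_format
#' @param plate A `plate_format`.
#' @export
plate_capacity <- function(plate) {
  stopifnot(inherits(plate, "plate_format"))
  plate$rows * plate$columns
}

#' @export
print.plate_format <- function(x, ...) {
  cat(sprintf("<plate_format> %s: %d rows x %d columns (%d wells)\n",
              x$label, x$rows, x$columns, plate_capacity(x)))
  invisible(x)
}

#' Well address helpers
#'
#' Wells are addressed in the canonical letter+number form used on plates:
#' `"A1"` is row 1, column 1. `well_name()` renders (row, column) pairs;
#' `parse_well()` inverts it. Both are vectorized and the pair is a bijection
#' for plates of up to 26 rows.
#'
#' @param row,column 1-based indices.
#' @return `well_name()`: character vector; `parse_well()`: data frame with
#'   integer columns `row` and `column`.
#' @examples
#' well_name(1, 1)        # "A1"
#' parse_well("H12")      # row 8, column 12
#' @export
well_name <- function(row, column) {
  if (any(row < 1L) || any(row > 26L) || any(column < 1L))
    cm_stop("well row must be in 1..26 and column >= 1", "cm_range_error")
  paste0(LETTERS[row], as.integer(column))
}

#' @rdname well_name
#' @param x Character vector of well names such as `"A1"`.
#' @export
parse_well <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regexec("^([A-Z])([0-9]+)$", x)
  parts <- regmatches(x, m)
  bad <- lengths(parts) != 3L
  if (any(bad))
    cm_stop(sprintf("malformed well address: %s",
                    paste(x[bad], collapse = ", ")), "cm_format_error")
  row <- match(vapply(parts, `[`, "", 2L), LETTERS)
  column <- as.integer(vapply(parts, `[`, "", 3L))
  if (any(column < 1L))
    cm_stop("well column must be >= 1", "cm_range_error")
  data.frame(row = row, column = column)
}

# canonicalize and range-check well names against a plate
check_wells <- function(plate, wells) {
  addr <- parse_well(wells)
  off <- addr$row > plate$rows | addr$column > plate$columns
  if (any(off))
    cm_stop(sprintf("well(s) outside the %dx%d plate: %s",
                    plate$rows, plate$columns,
                    paste(well_name(addr$row[off], addr$column[off]),
                          collapse = ", ")),
            "cm_range_error")
  well_name(addr$row, addr$column)
}

#' Describe a biological condition
#'
#' A condition groups the technical-replicate wells that received the same
#' biological treatment, together with its annotation (cell line, treatment
#' compound, dose). `assay_kind` records the geometry of the assay:
#' `"open_area"` for wound-healing-like data where the cell-free area shrinks
#' as cells migrate, `"covered_area"` where the measured area grows. The sign
#' convention is used by quality control to define the against-trend
#' direction; it never flips any data.
#'
#' @param name Condition name, unique within an experiment.
#' @param cell_line,treatment Free-text annotation.
#' @param dose Nonnegative dose value; `dose_unit` its unit text.
#' @param dose_unit Unit for `dose` (free text, e.g. `"uM"`).
#' @param assay_kind `"open_area"` or `"covered_area"`.
#' @param extra Named list of additional free-text metadata.
#' @param wells Character vector of well addresses (may start empty and be
#'   filled with [assign_wells()]).
#' @return An object of class `condition`.
#' @export
condition <- function(name, cell_line = "", treatment = "", dose = 0,
                      dose_unit = "", assay_kind = c("open_area", "covered_area"),
                      extra = list(), wells = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    cm_stop("condition 'name' must be a non-empty string", "cm_validation_error")
  assay_kind <- match.arg(assay_kind)
  dose <- check_number(dose, "dose", min = 0)
  if (length(extra) && (is.null(names(extra)) || any(!nzchar(names(extra)))))
    cm_stop("'extra' metadata must be a named list", "cm_validation_error")
  extra <- if (length(extra)) lapply(extra, as.character) else list()
  structure(list(name = name, cell_line = as.character(cell_line),
                 treatment = as.character(treatment), dose = dose,
                 dose_unit = as.character(dose_unit), assay_kind = assay_kind,
                 extra = extra,
                 wells = as.character(wells)),
            class = "condition")
}

#' Create a plate experiment
#'
#' An experiment ties a plate format to a set of annotated conditions and
#' records the measurement units. Conditions can be supplied here or added
#' with [add_condition()]; wells are attached with [assign_wells()].
#'
#' @param identifier Experiment identifier (free text).
#' @param project Project name.
#' @param date Experiment date (`Date` or ISO-8601 string).
#' @param plate A [plate_format()].
#' @param conditions List of [condition()] objects.
#' @param time_unit,area_unit Unit texts (defaults `"h"` and `"um2"`).
#' @return An object of class `experiment`.
#' @examples
#' exp <- experiment("exp1", plate = plate_format(8, 12))
#' exp <- add_condition(exp, condition("ctrl", cell_line = "MCF7"))
#' exp <- assign_wells(exp, "ctrl", c("A1", "A2", "A3"))
#' @export
experiment <- function(identifier, project = "", date = Sys.Date(), plate,
                       conditions = list(), time_unit = "h", area_unit = "um2") {
  if (!inherits(plate, "plate_format"))
    cm_stop("'plate' must be a plate_format", "cm_validation_error")
  date <- as.Date(date)
  exp <- structure(list(identifier = as.character(identifier),
                        project = as.character(project), date = date,
                        plate = plate, conditions = list(),
                        time_unit = as.character(time_unit),
                        area_unit = as.character(area_unit)),
                   class = "experiment")
  for (cond in conditions) exp <- add_condition(exp, cond)
  exp
}

#' @rdname experiment
#' @param exp An `experiment`.
#' @param cond A [condition()] to add; its name must be new and its wells (if
#'   any) on-plate and unassigned.
#' @export
add_condition <- function(exp, cond) {
  stopifnot(inherits(exp, "experiment"), inherits(cond, "condition"))
  if (cond$name %in% names(exp$conditions))
    cm_stop(sprintf("condition name '%s' already used", cond$name),
            "cm_conflict_error")
  wells <- cond$wells
  cond$wells <- character()
  exp$conditions[[cond$name]] <- cond
  if (length(wells)) exp <- assign_wells(exp, cond$name, wells)
  exp
}

# named character vector: well -> owning condition
assigned_wells <- function(exp) {
  out <- unlist(unname(lapply(exp$conditions, function(cond) {
    stats::setNames(rep(cond$name, length(cond$wells)), cond$wells)
  })))
  if (is.null(out)) out <- stats::setNames(character(), character())
  out
}

#' Assign technical-replicate wells to a condition
#'
#' Each well belongs to at most one condition (a well is one technical
#' replicate of that condition). Re-assigning a well to the condition that
#' already owns it is an idempotent no-op; assigning it to a different
#' condition is a conflict.
#'
#' @param exp An [experiment()].
#' @param condition_name Name of an existing condition.
#' @param wells Character vector of well addresses, e.g. `c("A1","A2")`.
#' @return The updated experiment.
#' @export
assign_wells <- function(exp, condition_name, wells) {
  stopifnot(inherits(exp, "experiment"))
  if (!condition_name %in% names(exp$conditions))
    cm_stop(sprintf("unknown condition '%s'", condition_name), "cm_lookup_error")
  wells <- check_wells(exp$plate, wells)
  if (anyDuplicated(wells))
    cm_stop("duplicated well in assignment request", "cm_conflict_error")
  owner <- assigned_wells(exp)
  taken <- wells %in% names(owner) & owner[wells] != condition_name
  if (any(taken))
    cm_stop(sprintf("well(s) already assigned to another condition: %s",
                    paste(wells[taken], collapse = ", ")),
            "cm_conflict_error")
  cur <- exp$conditions[[condition_name]]$wells
  exp$conditions[[condition_name]]$wells <- c(cur, setdiff(wells, cur))
  exp
}

#' Validate an experiment's invariants
#'
#' Checks that condition names are pairwise distinct, every condition has at
#' least one well (unless `require_wells = FALSE`), all wells lie on the
#' plate, and no well belongs to two conditions. Invisibly returns `TRUE`;
#' otherwise signals a validation error naming the violated invariant.
#'
#' @param exp An [experiment()].
#' @param require_wells Require every condition to own at least one well
#'   (the finalized-experiment invariant).
#' @export
validate_experiment <- function(exp, require_wells = TRUE) {
  stopifnot(inherits(exp, "experiment"))
  nm <- names(exp$conditions)
  if (anyDuplicated(nm))
    cm_stop("condition names are not pairwise distinct", "cm_validation_error")
  for (cond in exp$conditions) {
    if (require_wells && length(cond$wells) == 0L)
      cm_stop(sprintf("condition '%s' has no wells assigned", cond$name),
              "cm_validation_error")
    if (length(cond$wells)) check_wells(exp$plate, cond$wells)
  }
  all_wells <- unlist(lapply(exp$conditions, `[[`, "wells"))
  if (anyDuplicated(all_wells))
    cm_stop(sprintf("well(s) assigned to more than one condition: %s",
                    paste(unique(all_wells[duplicated(all_wells)]),
                          collapse = ", ")),
            "cm_validation_error")
  invisible(TRUE)
}

#' @export
print.experiment <- function(x, ...) {
  cat(sprintf("<experiment> %s (%s, %s)\n", x$identifier, x$project, x$date))
  cat(sprintf("  plate: %s (%dx%d); units: time [%s], area [%s]\n",
              x$plate$label, x$plate$rows, x$plate$columns,
              x$time_unit, x$area_unit))
  for (cond in x$conditions)
    cat(sprintf("  condition '%s' (%s): %d well(s) %s\n", cond$name,
                cond$assay_kind, length(cond$wells),
                paste(cond$wells, collapse = " ")))
  invisible(x)
}

#' Render a laboratory setup sheet
#'
#' Produces a human-readable markdown grid of the plate with per-well
#' condition labels, followed by a legend with each condition's metadata.
#' Intended to be printed and taken to the bench.
#'
#' @param exp An [experiment()]; it must validate.
#' @param path Optional file to write the sheet to.
#' @return Character vector of markdown lines (invisibly if `path` given).
#' @export
render_setup_sheet <- function(exp, path = NULL) {
  validate_experiment(exp)
  owner <- assigned_wells(exp)
  header <- c("", as.character(seq_len(exp$plate$columns)))
  grid <- matrix(".", nrow = exp$plate$rows, ncol = exp$plate$columns)
  if (length(owner)) {
    addr <- parse_well(names(owner))
    grid[cbind(addr$row, addr$column)] <- unname(owner)
  }
  body <- lapply(seq_len(exp$plate$rows), function(r)
    c(LETTERS[r], grid[r, ]))
  tab <- rbind(header, c("---", rep("---", exp$plate$columns)),
               do.call(rbind, body))
  grid_lines <- apply(tab, 1L, function(row)
    paste0("| ", paste(row, collapse = " | "), " |"))
  legend <- unlist(lapply(exp$conditions, function(cond) {
    extras <- if (length(cond$extra))
      paste(sprintf("%s=%s", names(cond$extra), unlist(cond$extra)),
            collapse = "; ")
    else ""
    c(sprintf("- **%s**: cell line: %s; treatment: %s; dose: %g %s; assay: %s%s",
              cond$name, cond$cell_line, cond$treatment, cond$dose,
              cond$dose_unit, cond$assay_kind,
              if (nzchar(extras)) paste0("; ", extras) else ""),
      sprintf("  wells: %s", paste(cond$wells, collapse = ", ")))
  }))
  lines <- c(sprintf("# Plate setup: %s", exp$identifier),
             "",
             sprintf("Project: %s  |  Date: %s  |  Plate: %s",
                     exp$project, format(exp$date), exp$plate$label),
             "", grid_lines, "", "## Conditions", "", legend)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
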