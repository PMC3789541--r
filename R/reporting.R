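# Structured analysis reports.
#
# A report is a *view* of pipeline output -- it never recomputes anything,
# so every number it shows equals the corresponding result exactly.
# Markdown is the canonical, byte-deterministic rendering; HTML is a
# minimal wrapper; PDF requires an external pandoc and fails with a clear
# capability error when none is installed.

fmt_slope <- function(x) formatC(signif(x, 4), format = "g", digits = 4)

fmt_p <- function(p) {
  ifelse(p < 0.001, sprintf("%.2e", p),
         formatC(signif(p, 3), format = "g", digits = 3))
}

md_table <- function(df, digits_fun = list()) {
  if (!nrow(df)) return("*(none)*")
  cells <- vapply(names(df), function(nm) {
    col <- df[[nm]]
    if (nm %in% names(digits_fun)) digits_fun[[nm]](col)
    else if (is.numeric(col)) formatC(signif(col, 6), format = "g", digits = 6)
    else as.character(col)
  }, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep(" --- |", ncol(df)), collapse = "")),
    apply(cells, 1L, function(row)
      paste0("| ", paste(row, collapse = " | "), " |")))
}

#' Assemble the analysis report
#'
#' Collects the experimental design, data summary, QC log and decisions,
#' per-replicate fits, condition velocities and pairwise statistics into a
#' single structured object with deterministic ordering (conditions in
#' experiment order, wells row-major). Each section is a verbatim view of
#' the pipeline output passed in.
#'
#' @param ana A [analyze_experiment()] result (carries the loaded
#'   experiment, QC log, fits and comparisons).
#' @param config Optional extra provenance entries (e.g. the simulation
#'   seed) merged into the configuration snapshot.
#' @return Object of class `analysis_report`.
#' @export
build_report <- function(ana, config = list()) {
  if (missing(ana) || !inherits(ana, "migration_analysis"))
    cm_stop("report assembly needs a completed migration_analysis",
            "cm_assembly_error")
  for (part in c("loaded", "qc", "results"))
    if (is.null(ana[[part]]))
      cm_stop(sprintf("analysis is missing its '%s' section", part),
              "cm_assembly_error")
  exp <- ana$loaded$experiment
  tabs <- results_tables(ana)
  series <- order_series(ana$loaded$series)
  data_summary <- data.frame(
    well = vapply(series, `[[`, "", "well"),
    source_label = vapply(series, `[[`, "", "source_label"),
    n_points = vapply(series, function(s) length(s$time), 0L),
    time_min = vapply(series, function(s) min(s$time), 0),
    time_max = vapply(series, function(s) max(s$time), 0),
    stringsAsFactors = FALSE)
  structure(list(experiment = exp,
                 data_summary = data_summary,
                 qc_log = ana$qc$qc_log,
                 excluded_wells = ana$qc$excluded_wells,
                 fits = tabs$fits,
                 conditions = tabs$conditions,
                 comparisons = tabs$comparisons,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("cellmigrate")),
                   config = utils::modifyList(ana$config, config))),
            class = "analysis_report")
}

#' Render an analysis report
#'
#' Markdown is the canonical form: rendering the same report twice yields
#' identical bytes, which makes reports diffable and testable. HTML embeds
#' the same content in a minimal page. PDF conversion needs `pandoc` on the
#' PATH and raises a capability error otherwise.
#'
#' @param report A [build_report()] result.
#' @param format `"markdown"`, `"html"` or `"pdf"`.
#' @param path Output file; required for `"pdf"`, optional otherwise.
#' @return The rendered document as a character string (markdown/html), or
#'   the output path (pdf). Invisibly when written to `path`.
#' @export
render_report <- function(report, format = c("markdown", "html", "pdf"),
                          path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format)
  md <- render_markdown(report)
  if (format == "markdown") {
    if (!is.null(path)) { writeLines(md, path); return(invisible(md)) }
    return(md)
  }
  if (format == "html") {
    esc <- function(x) gsub(">", "&gt;", gsub("<", "&lt;", gsub("&", "&amp;", x)))
    html <- paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
                   "<title>", esc(report$experiment$identifier),
                   "</title></head>\n<body>\n<pre>\n", esc(md),
                   "\n</pre>\n</body></html>\n")
    if (!is.null(path)) { writeLines(html, path); return(invisible(html)) }
    return(html)
  }
  # pdf
  pandoc <- Sys.which("pandoc")
  if (!nzchar(pandoc))
    cm_stop("PDF rendering requires 'pandoc' on the PATH; render markdown or html instead",
            "cm_capability_error")
  if (is.null(path))
    cm_stop("'path' is required for PDF output", "cm_value_error")
  mdfile <- tempfile(fileext = ".md")
  on.exit(unlink(mdfile))
  writeLines(md, mdfile)
  status <- system2(pandoc, c(mdfile, "-o", shQuote(path)))
  if (status != 0)
    cm_stop("pandoc failed to produce the PDF", "cm_capability_error")
  invisible(path)
}

render_markdown <- function(report) {
  exp <- report$experiment
  cond_meta <- do.call(rbind, lapply(exp$conditions, function(cond)
    data.frame(condition = cond$name, cell_line = cond$cell_line,
               treatment = cond$treatment,
               dose = sprintf("%g %s", cond$dose, cond$dose_unit),
               assay_kind = cond$assay_kind,
               wells = paste(cond$wells, collapse = " "),
               stringsAsFactors = FALSE)))
  qc_lines <- if (nrow(report$qc_log) == 0L) {
    "0 flags."
  } else {
    c(sprintf("%d flag(s):", nrow(report$qc_log)), "",
      md_table(report$qc_log, digits_fun = list(
        value = function(x) formatC(signif(x, 6), format = "g", digits = 6))))
  }
  cfg <- report$provenance$config
  cfg_lines <- vapply(names(cfg), function(nm)
    sprintf("- %s: %s", nm,
            if (is.null(cfg[[nm]])) "default"
            else paste(format(cfg[[nm]]), collapse = ", ")), "")
  lines <- c(
    sprintf("# Migration analysis report: %s", exp$identifier),
    "",
    "## Experimental design",
    "",
    sprintf("Project: %s  |  Date: %s  |  Plate: %s (%dx%d)",
            exp$project, format(exp$date), exp$plate$label,
            exp$plate$rows, exp$plate$columns),
    sprintf("Units: time [%s], area [%s]", exp$time_unit, exp$area_unit),
    "",
    md_table(cond_meta),
    "",
    "## Acquired data",
    "",
    md_table(report$data_summary),
    "",
    "## Quality control",
    "",
    qc_lines,
    "",
    if (length(report$excluded_wells))
      sprintf("Replicates excluded from analysis: %s",
              paste(report$excluded_wells, collapse = ", "))
    else "No replicates excluded.",
    "",
    "## Replicate fits",
    "",
    md_table(report$fits, digits_fun = list(
      slope = fmt_slope, intercept = fmt_slope,
      r_squared = function(x) formatC(signif(x, 4), format = "g", digits = 4),
      std_error = fmt_slope)),
    "",
    "## Condition velocities",
    "",
    md_table(report$conditions,
             digits_fun = list(median_velocity = fmt_slope)),
    "",
    "## Statistical evaluation",
    "",
    md_table(report$comparisons,
             digits_fun = list(p_raw = fmt_p, p_adjusted = fmt_p)),
    "",
    "## Provenance",
    "",
    sprintf("- package version: %s", report$provenance$package_version),
    cfg_lines,
    "")
  paste(lines, collapse = "\n")
}
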