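# XML exchange format (schema_version 1.0).
#
# One document carries either a set-up template (plate + conditions, no
# measurements) or a full experiment (template plus a <data> section of
# per-well series). The schema ships in inst/extdata/experiment-schema.xsd
# and is validated on import. Numbers are serialized with 17 significant
# digits so export -> import is value-exact for doubles.

XML_SCHEMA_VERSION <- "1.0"

num17 <- function(x) sprintf("%.17g", x)

schema_path <- function() {
  system.file("extdata", "experiment-schema.xsd", package = "cellmigrate",
              mustWork = TRUE)
}

# Accept a path, a literal XML string, or an xml_document; validate against
# the shipped XSD and report violations with their location.
read_experiment_doc <- function(x) {
  doc <- if (inherits(x, "xml_document")) {
    x
  } else if (is.character(x) && length(x) == 1L) {
    parsed <- tryCatch(xml2::read_xml(x), error = function(e) e)
    if (inherits(parsed, "error"))
      cm_stop(sprintf("cannot parse XML document: %s",
                      conditionMessage(parsed)), "cm_parse_error")
    parsed
  } else {
    cm_stop("expected a file path, XML string or xml_document",
            "cm_parse_error")
  }
  ok <- xml2::xml_validate(doc, xml2::read_xml(schema_path()))
  if (!isTRUE(ok))
    cm_stop(paste0("document does not match the experiment schema: ",
                   paste(attr(ok, "errors"), collapse = "; ")),
            "cm_parse_error")
  doc
}

add_setup_nodes <- function(doc, exp) {
  xml2::xml_set_attrs(doc, c(schema_version = XML_SCHEMA_VERSION,
                             identifier = exp$identifier,
                             project = exp$project,
                             date = format(exp$date, "%Y-%m-%d"),
                             time_unit = exp$time_unit,
                             area_unit = exp$area_unit))
  xml2::xml_add_child(doc, "plate", rows = as.character(exp$plate$rows),
                      columns = as.character(exp$plate$columns),
                      label = exp$plate$label)
  conds <- xml2::xml_add_child(doc, "conditions")
  for (cond in exp$conditions) {
    cnode <- xml2::xml_add_child(conds, "condition", name = cond$name,
                                 cell_line = cond$cell_line,
                                 treatment = cond$treatment,
                                 dose = num17(cond$dose),
                                 dose_unit = cond$dose_unit,
                                 assay_kind = cond$assay_kind)
    if (length(cond$extra)) {
      mnode <- xml2::xml_add_child(cnode, "metadata")
      for (key in names(cond$extra)) {
        e <- xml2::xml_add_child(mnode, "entry", key = key)
        xml2::xml_set_text(e, cond$extra[[key]])
      }
    }
    wnode <- xml2::xml_add_child(cnode, "wells")
    for (w in cond$wells) {
      e <- xml2::xml_add_child(wnode, "well")
      xml2::xml_set_text(e, w)
    }
  }
  invisible(doc)
}

#' Export an experiment set-up template as XML
#'
#' Writes the plate geometry and every condition with its full annotation and
#' well assignments -- but no measurement data -- so that the design can be
#' shared between researchers and re-imported with
#' [import_setup_template()]. The experiment must validate first.
#'
#' @param exp An [experiment()]; validated before export.
#' @param path Optional file to write to (UTF-8 XML).
#' @return An `xml2::xml_document` (invisibly if `path` is given).
#' @seealso [import_setup_template()], [export_experiment_xml()]
#' @export
export_setup_template <- function(exp, path = NULL) {
  validate_experiment(exp)
  doc <- xml2::xml_new_root("experiment")
  add_setup_nodes(doc, exp)
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

# xml_attr() yields NA for absent attributes; map that to a default
attr_or <- function(node, name, default = "") {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

parse_setup <- function(doc) {
  root <- xml2::xml_root(doc)
  plate_node <- xml2::xml_find_first(root, "./plate")
  plate <- plate_format(as.integer(xml2::xml_attr(plate_node, "rows")),
                        as.integer(xml2::xml_attr(plate_node, "columns")),
                        attr_or(plate_node, "label", NULL))
  exp <- experiment(identifier = attr_or(root, "identifier"),
                    project = attr_or(root, "project"),
                    date = attr_or(root, "date", NA),
                    plate = plate,
                    time_unit = attr_or(root, "time_unit", "h"),
                    area_unit = attr_or(root, "area_unit", "um2"))
  for (cnode in xml2::xml_find_all(root, "./conditions/condition")) {
    entries <- xml2::xml_find_all(cnode, "./metadata/entry")
    extra <- stats::setNames(as.list(xml2::xml_text(entries)),
                             xml2::xml_attr(entries, "key"))
    wells <- xml2::xml_text(xml2::xml_find_all(cnode, "./wells/well"))
    cond <- condition(name = xml2::xml_attr(cnode, "name"),
                      cell_line = attr_or(cnode, "cell_line"),
                      treatment = attr_or(cnode, "treatment"),
                      dose = as.numeric(attr_or(cnode, "dose", "0")),
                      dose_unit = attr_or(cnode, "dose_unit"),
                      assay_kind = attr_or(cnode, "assay_kind", "open_area"),
                      extra = extra, wells = wells)
    exp <- add_condition(exp, cond)
  }
  validate_experiment(exp)
  exp
}

#' Import an experiment set-up template
#'
#' Reads a template produced by [export_setup_template()] (a path, XML string
#' or `xml_document`), validates it against the shipped schema, and
#' reconstructs the [experiment()] field-for-field. Schema violations raise a
#' parse error naming the offending element; duplicate condition names or
#' conflicting well assignments raise validation/conflict errors.
#'
#' @param x Path, XML string or `xml2::xml_document`.
#' @return An [experiment()].
#' @export
import_setup_template <- function(x) {
  parse_setup(read_experiment_doc(x))
}
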