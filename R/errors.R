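# Classed conditions so callers can distinguish failure modes programmatically.
# All package errors also carry class "cellmigrate_error".
cm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cellmigrate_error"), call = call))
}

cm_warn <- function(msg, class = "cellmigrate_warning") {
  warning(warningCondition(msg, class = c(class, "cellmigrate_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar checks used by the constructors
check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    cm_stop(sprintf("'%s' must be a single positive whole number", name),
            "cm_validation_error")
  as.integer(x)
}

check_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    cm_stop(sprintf("'%s' must be a single finite number%s", name,
                    if (is.finite(min)) sprintf(" >= %g", min) else ""),
            "cm_validation_error")
  as.numeric(x)
}
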