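# Pluggable analysis algorithms.
#
# Five slots mirror the analysis steps that admit alternative methods:
# distance metrics for replicate screening, statistical tests for condition
# comparison, kernels for the density estimator, outlier rules for the
# artifact cutoff, and multiple-testing correction methods. Each slot has a
# registered default; new implementations become selectable by name from
# every entry point that takes the corresponding argument.

.plugin_registry <- new.env(parent = emptyenv())

PLUGIN_SLOTS <- c("distance_metric", "statistical_test", "kde_kernel",
                  "outlier_rule", "correction_method")

reset_plugins <- function() {
  for (slot in PLUGIN_SLOTS) assign(slot, list(), envir = .plugin_registry)

  register_plugin("distance_metric", "euclidean",
                  function(x, y) sqrt(sum((x - y)^2)))
  register_plugin("distance_metric", "manhattan",
                  function(x, y) sum(abs(x - y)))

  register_plugin("statistical_test", "mann_whitney",
                  function(a, b, ...) mann_whitney_u(a, b, ...))

  register_plugin("kde_kernel", "gaussian",
                  list(density = stats::dnorm, cdf = stats::pnorm))
  register_plugin("kde_kernel", "epanechnikov", list(
    density = function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0),
    cdf = function(u) ifelse(u < -1, 0,
                             ifelse(u > 1, 1, 0.5 + 0.75 * (u - u^3 / 3)))))

  # rule(kde, delta, alpha, direction) -> is this delta in the extreme
  # against-trend tail? direction is +1 (upper tail) or -1 (lower tail)
  register_plugin("outlier_rule", "tail_mass",
                  function(kde, delta, alpha, direction) {
                    tail_p <- if (direction > 0) 1 - kde_cdf(kde, delta)
                              else kde_cdf(kde, delta)
                    tail_p < alpha
                  })

  register_plugin("correction_method", "bonferroni",
                  function(p) stats::p.adjust(p, method = "bonferroni"))
  register_plugin("correction_method", "benjamini_hochberg",
                  function(p) stats::p.adjust(p, method = "BH"))
  invisible(NULL)
}

#' Register, look up and list analysis plugins
#'
#' The analysis architecture is pluggable: a new distance metric,
#' statistical test, KDE kernel, outlier rule or correction method
#' registered here is immediately selectable by name wherever the
#' corresponding argument is accepted (e.g. `metric` in
#' [replicate_distances()], `kernel` in [fit_kde()], `method` in
#' [adjust_pvalues()]).
#'
#' @param slot One of `"distance_metric"`, `"statistical_test"`,
#'   `"kde_kernel"`, `"outlier_rule"`, `"correction_method"`.
#' @param name Implementation name; must be unused in the slot.
#' @param impl The implementation (a function, or for `kde_kernel` a list
#'   with elements `density` and `cdf`).
#' @return `register_plugin()` returns `impl` invisibly. `get_plugin()`
#'   returns the registered implementation. `list_plugins()` returns a named
#'   list of character vectors of implementation names.
#' @examples
#' list_plugins("distance_metric")
#' @export
register_plugin <- function(slot, name, impl) {
  if (!slot %in% PLUGIN_SLOTS)
    cm_stop(sprintf("unknown plugin slot '%s' (have: %s)", slot,
                    paste(PLUGIN_SLOTS, collapse = ", ")), "cm_lookup_error")
  reg <- get(slot, envir = .plugin_registry)
  if (name %in% names(reg))
    cm_stop(sprintf("plugin '%s' already registered in slot '%s'", name, slot),
            "cm_conflict_error")
  reg[[name]] <- impl
  assign(slot, reg, envir = .plugin_registry)
  invisible(impl)
}

#' @rdname register_plugin
#' @export
get_plugin <- function(slot, name) {
  if (!slot %in% PLUGIN_SLOTS)
    cm_stop(sprintf("unknown plugin slot '%s'", slot), "cm_lookup_error")
  reg <- get(slot, envir = .plugin_registry)
  if (!name %in% names(reg))
    cm_stop(sprintf("no plugin '%s' in slot '%s' (have: %s)", name, slot,
                    paste(names(reg), collapse = ", ")), "cm_lookup_error")
  reg[[name]]
}

#' @rdname register_plugin
#' @export
list_plugins <- function(slot = NULL) {
  slots <- if (is.null(slot)) PLUGIN_SLOTS else slot
  out <- lapply(slots, function(s) names(get_plugin_slot(s)))
  names(out) <- slots
  if (!is.null(slot) && length(slot) == 1L) out[[1L]] else out
}

get_plugin_slot <- function(slot) {
  if (!slot %in% PLUGIN_SLOTS)
    cm_stop(sprintf("unknown plugin slot '%s'", slot), "cm_lookup_error")
  get(slot, envir = .plugin_registry)
}

.onLoad <- function(libname, pkgname) {
  reset_plugins()
}
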