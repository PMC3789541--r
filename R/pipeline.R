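#' Run the full migration analysis pipeline
#'
#' Normalization, two-stage quality control, per-replicate velocity
#' regression, condition medians, and pairwise Mann-Whitney comparison with
#' multiple-testing correction -- the complete path from a loaded
#' experiment to statistics.
#'
#' @param loaded A [loaded_experiment()].
#' @param conditions Conditions to compare pairwise (default all; a single
#'   condition skips the comparison step).
#' @param alpha,k_mad,kernel,bandwidth,metric,policy,decisions,pool Passed
#'   to [run_qc()].
#' @param correction Multiple-testing method, see [adjust_pvalues()].
#' @param sig_level Significance level for adjusted p-values.
#' @param mode Mann-Whitney mode, see [mann_whitney_u()].
#' @param r2_threshold Optional minimum replicate R^2; fits below it are
#'   dropped before the median (off by default).
#' @return Object of class `migration_analysis`: `loaded`, `qc`, `results`
#'   (list of [condition_velocity()] objects), `comparisons` (or `NULL`),
#'   and `config`.
#' @examples
#' spec <- sim_spec(list(list(name = "ctrl", true_slope = -10, n_replicates = 3),
#'                       list(name = "drug", true_slope = -2, n_replicates = 3)),
#'                  noise_sd = 0.5, seed = 7)
#' ana <- analyze_experiment(simulate_experiment(spec))
#' ana$results$ctrl$median_velocity
#' @export
analyze_experiment <- function(loaded, conditions = NULL, alpha = 0.05,
                               k_mad = 3, kernel = "gaussian",
                               bandwidth = "auto", metric = "euclidean",
                               policy = "accept_all", decisions = NULL,
                               pool = "condition",
                               correction = "benjamini_hochberg",
                               sig_level = 0.05, mode = "auto",
                               r2_threshold = NULL) {
  stopifnot(inherits(loaded, "loaded_experiment"))
  qc <- run_qc(loaded, alpha = alpha, k_mad = k_mad, kernel = kernel,
               bandwidth = bandwidth, metric = metric, policy = policy,
               decisions = decisions, pool = pool)
  results <- list()
  for (cond in loaded$experiment$conditions) {
    wells <- setdiff(cond$wells, qc$excluded_wells)
    fits <- lapply(wells, function(w) fit_replicate(qc$replicates[[w]]))
    if (!is.null(r2_threshold))
      fits <- Filter(function(f) f$r_squared >= r2_threshold, fits)
    if (length(fits))
      results[[cond$name]] <- condition_velocity(fits, cond$name)
  }
  selection <- conditions %||% names(results)
  comparisons <- if (length(selection) >= 2L)
    compare_conditions(results, selection, method = correction,
                       alpha = sig_level, mode = mode)
  structure(list(loaded = loaded, qc = qc, results = results,
                 comparisons = comparisons,
                 config = list(alpha = alpha, k_mad = k_mad, kernel = kernel,
                               bandwidth = bandwidth, metric = metric,
                               policy = policy, pool = pool,
                               correction = correction,
                               sig_level = sig_level, mode = mode,
                               r2_threshold = r2_threshold)),
            class = "migration_analysis")
}

#' @export
print.migration_analysis <- function(x, ...) {
  cat(sprintf("<migration_analysis> %s\n", x$loaded$experiment$identifier))
  print(x$qc)
  for (res in x$results) print(res)
  if (!is.null(x$comparisons)) {
    cat(sprintf("pairwise Mann-Whitney (%s-adjusted):\n",
                attr(x$comparisons, "method")))
    print.data.frame(x$comparisons)
  }
  invisible(x)
}

#' Tabulate analysis results
#'
#' @param ana A [analyze_experiment()] result.
#' @return List of data frames: `fits` (one row per replicate), `conditions`
#'   (one row per condition with the median velocity), `comparisons` (one
#'   row per tested pair; zero rows when fewer than two conditions).
#' @export
results_tables <- function(ana) {
  stopifnot(inherits(ana, "migration_analysis"))
  fits <- do.call(rbind, unlist(lapply(ana$results, function(res)
    lapply(res$fits, function(f)
      data.frame(condition = res$condition, well = f$well, slope = f$slope,
                 intercept = f$intercept, r_squared = f$r_squared,
                 std_error = f$std_error, n_points = f$n_points,
                 stringsAsFactors = FALSE))), recursive = FALSE))
  rownames(fits) <- NULL
  conditions <- data.frame(
    condition = vapply(ana$results, `[[`, "", "condition"),
    n_replicates = vapply(ana$results, function(r) length(r$fits), 0L),
    median_velocity = vapply(ana$results, `[[`, 0, "median_velocity"),
    stringsAsFactors = FALSE)
  rownames(conditions) <- NULL
  comparisons <- if (is.null(ana$comparisons))
    data.frame(condition_a = character(), condition_b = character(),
               u_statistic = numeric(), p_raw = numeric(),
               p_adjusted = numeric(), significant = logical())
  else as.data.frame(ana$comparisons)
  list(fits = fits, conditions = conditions, comparisons = comparisons)
}

#' Write the per-replicate and pairwise result tables as TSV
#'
#' Writes `<stem>_fits.tsv`, `<stem>_conditions.tsv` and
#' `<stem>_comparisons.tsv` at full numeric precision.
#'
#' @param ana A [analyze_experiment()] result.
#' @param stem Output path stem.
#' @return Invisibly, the paths written.
#' @export
write_results_tsv <- function(ana, stem) {
  tabs <- results_tables(ana)
  paths <- sprintf("%s_%s.tsv", stem, names(tabs))
  for (k in seq_along(tabs))
    utils::write.table(tabs[[k]], paths[k], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(paths)
}
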