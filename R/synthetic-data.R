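# Synthetic wound-healing experiments with known ground truth.
#
# The generator emulates the data arriving from image processing: per-well
# area-versus-time trajectories on a multi-well plate. The mean model is
# linear in normalized units -- area(t) = A0 * (1 + slope/100 * t) -- with
# additive Gaussian measurement noise (truncated so areas stay positive),
# optional against-trend artifact spikes at random single time points
# (mimicking segmentation failures), and optional divergent replicates
# whose true slope is offset (mimicking a technically failed well). Every
# draw descends deterministically from one master seed via a fixed
# per-series derivation, so adding a condition never perturbs another
# condition's data.

#' Specify a synthetic experiment
#'
#' @param conditions List of condition specs; each a list with `name`,
#'   `true_slope` (percent of t0 area per time unit; negative for a closing
#'   open area), `n_replicates` (>= 1), and optional `assay_kind`
#'   (default `"open_area"`).
#' @param plate A [plate_format()] (default 96-well); wells are assigned
#'   row-major from A1.
#' @param time_grid Time points shared by all wells (default hourly,
#'   0--8 h, over which a typical wound at -10 percent per hour closes to
#'   about 20 percent without touching the positivity floor; >= 3 points).
#' @param baseline_area Area at time 0 in area units (default 10000).
#' @param noise_sd Measurement noise SD in percent of the t0 area
#'   (default 2).
#' @param artifact_rate Per-step probability of an injected artifact spike
#'   (default 0, i.e. clean data).
#' @param artifact_magnitude `c(mean, sd)` of the spike magnitude in
#'   percent units, drawn truncated-positive (default `c(15, 3)`).
#' @param divergent_per_condition Number of divergent replicates per
#'   condition (the last wells of the condition; default 0).
#' @param divergent_offset Slope offset added to divergent replicates, in
#'   percent per time unit (default +8).
#' @param seed Master seed (integer).
#' @param date Experiment date; fixed by default so identical specs export
#'   byte-identical XML.
#' @return Object of class `sim_spec`.
#' @examples
#' spec <- sim_spec(list(list(name = "ctrl", true_slope = -10,
#'                            n_replicates = 3)), seed = 1)
#' @export
sim_spec <- function(conditions, plate = plate_format(8, 12),
                     time_grid = seq(0, 8), baseline_area = 10000,
                     noise_sd = 2, artifact_rate = 0,
                     artifact_magnitude = c(15, 3),
                     divergent_per_condition = 0, divergent_offset = 8,
                     seed = 1L, date = as.Date("2000-01-01")) {
  stopifnot(inherits(plate, "plate_format"))
  time_grid <- as.numeric(time_grid)
  if (length(time_grid) < 3L)
    cm_stop("'time_grid' needs at least 3 points", "cm_value_error")
  if (any(diff(time_grid) <= 0) || any(time_grid < 0))
    cm_stop("'time_grid' must be nonnegative and strictly increasing",
            "cm_value_error")
  check_number(baseline_area, "baseline_area")
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(artifact_rate, "artifact_rate", min = 0)
  if (artifact_rate > 1)
    cm_stop("'artifact_rate' must be in [0, 1]", "cm_value_error")
  conds <- lapply(conditions, function(cd) {
    if (is.null(cd$name) || is.null(cd$true_slope) || is.null(cd$n_replicates))
      cm_stop("each condition spec needs 'name', 'true_slope', 'n_replicates'",
              "cm_value_error")
    cd$n_replicates <- check_count(cd$n_replicates, "n_replicates")
    cd$assay_kind <- cd$assay_kind %||% "open_area"
    cd
  })
  total <- sum(vapply(conds, `[[`, 1L, "n_replicates"))
  if (total > plate_capacity(plate))
    cm_stop("more replicates than wells on the plate", "cm_value_error")
  structure(list(conditions = conds, plate = plate, time_grid = time_grid,
                 baseline_area = baseline_area, noise_sd = noise_sd,
                 artifact_rate = artifact_rate,
                 artifact_magnitude = artifact_magnitude,
                 divergent_per_condition = as.integer(divergent_per_condition),
                 divergent_offset = divergent_offset,
                 seed = as.integer(seed), date = as.Date(date)),
            class = "sim_spec")
}

# deterministic per-series seed; keeps streams independent of how many other
# conditions/replicates exist (counter-based splitting of the master seed)
derive_seed <- function(seed, cond_idx, rep_idx) {
  as.integer((as.double(seed) + 7919 * cond_idx + 104729 * rep_idx) %%
               2147483647)
}

#' Simulate a complete experiment from a spec
#'
#' Generates the plate layout, condition annotation and one trajectory per
#' replicate well according to the model described in [sim_spec()]. Areas
#' are truncated below at 0.1 percent of the baseline so the positivity
#' invariant always holds. Identical specs (including seed) give identical
#' output, byte-for-byte through XML export.
#'
#' @param spec A [sim_spec()].
#' @return A [loaded_experiment()] with attribute `"truth"`: a list with
#'   `replicates` (data frame: condition, well, true_slope -- the effective
#'   slope including any divergent offset -- and divergent flag) and
#'   `artifacts` (data frame: well, source_label, step, magnitude).
#' @export
simulate_experiment <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  exp <- experiment(identifier = sprintf("sim-seed%d", spec$seed),
                    project = "synthetic", date = spec$date,
                    plate = spec$plate, time_unit = "h", area_unit = "um2")
  t <- spec$time_grid
  n <- length(t)
  A0 <- spec$baseline_area
  floor_area <- 1e-3 * A0
  well_cursor <- 0L
  truth_rows <- list()
  artifact_rows <- list()
  series <- list()

  for (ci in seq_along(spec$conditions)) {
    cd <- spec$conditions[[ci]]
    wells <- vapply(well_cursor + seq_len(cd$n_replicates), function(k) {
      row <- (k - 1L) %/% spec$plate$columns + 1L
      col <- (k - 1L) %% spec$plate$columns + 1L
      well_name(row, col)
    }, "")
    well_cursor <- well_cursor + cd$n_replicates
    exp <- add_condition(exp, condition(cd$name,
                                        cell_line = cd$cell_line %||% "",
                                        treatment = cd$treatment %||% "",
                                        dose = cd$dose %||% 0,
                                        dose_unit = cd$dose_unit %||% "",
                                        assay_kind = cd$assay_kind,
                                        wells = wells))
    n_div <- min(spec$divergent_per_condition, cd$n_replicates)
    for (ri in seq_len(cd$n_replicates)) {
      divergent <- ri > cd$n_replicates - n_div
      slope <- cd$true_slope + if (divergent) spec$divergent_offset else 0
      set.seed(derive_seed(spec$seed, ci, ri))
      clean <- A0 * (1 + slope / 100 * t)
      eps <- if (spec$noise_sd > 0)
        stats::rnorm(n, 0, spec$noise_sd * A0 / 100) else numeric(n)
      area <- clean + eps
      if (spec$artifact_rate > 0) {
        # isolated single-point spikes: at an artifact step the measured
        # area jumps against the trend by the spike magnitude relative to
        # the previous point, as if segmentation momentarily failed
        hit <- which(stats::runif(n - 1L) < spec$artifact_rate) + 1L
        if (length(hit) > 1L) hit <- hit[c(TRUE, diff(hit) > 1L)]
        for (idx in hit) {
          mag <- abs(stats::rnorm(1, spec$artifact_magnitude[1L],
                                  spec$artifact_magnitude[2L]))
          sgn <- if (cd$assay_kind == "open_area") 1 else -1
          area[idx] <- clean[idx - 1L] + sgn * mag * A0 / 100 + eps[idx]
          artifact_rows[[length(artifact_rows) + 1L]] <- data.frame(
            well = wells[ri], source_label = "sim", step = idx - 1L,
            magnitude = mag, stringsAsFactors = FALSE)
        }
      }
      area <- pmax(area, floor_area)
      series[[length(series) + 1L]] <- well_series(wells[ri], "sim", t, area)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        condition = cd$name, well = wells[ri], true_slope = slope,
        divergent = divergent, stringsAsFactors = FALSE)
    }
  }
  loaded <- loaded_experiment(exp, series)
  attr(loaded, "truth") <- list(
    replicates = do.call(rbind, truth_rows),
    artifacts = if (length(artifact_rows)) do.call(rbind, artifact_rows)
    else data.frame(well = character(), source_label = character(),
                    step = integer(), magnitude = numeric(),
                    stringsAsFactors = FALSE))
  loaded
}

#' Write a simulated (or real) experiment as a fixture file tree
#'
#' Writes one TSV per (well, source_label) in the generic two-column
#' dialect read by [read_well_file()], the full experiment XML, and -- when
#' the experiment carries simulation ground truth -- a
#' `ground_truth_synthetic.tsv` table. Reading the tree back reproduces the
#' experiment exactly; identical inputs produce byte-identical trees.
#'
#' @param loaded A [loaded_experiment()].
#' @param dir Target directory (created if needed).
#' @param overwrite Overwrite existing files (default `FALSE`: colliding
#'   files are an error).
#' @return Invisibly, the paths written.
#' @export
write_fixture_files <- function(loaded, dir, overwrite = FALSE) {
  stopifnot(inherits(loaded, "loaded_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    cm_stop(sprintf("cannot create directory '%s'", dir), "cm_io_error")
  series <- order_series(loaded$series)
  files <- c(vapply(series, function(ts)
    file.path(dir, sprintf("%s_%s.tsv", ts$well, ts$source_label)), ""),
    file.path(dir, "experiment.xml"))
  truth <- attr(loaded, "truth")
  if (!is.null(truth))
    files <- c(files, file.path(dir, "ground_truth_synthetic.tsv"))
  clash <- files[file.exists(files)]
  if (length(clash) && !overwrite)
    cm_stop(sprintf("refusing to overwrite existing file(s): %s",
                    paste(basename(clash), collapse = ", ")), "cm_io_error")
  for (k in seq_along(series)) {
    ts <- series[[k]]
    writeLines(c("time\tarea",
                 sprintf("%s\t%s", num17(ts$time), num17(ts$area))),
               files[k])
  }
  export_experiment_xml(loaded, file.path(dir, "experiment.xml"))
  if (!is.null(truth)) {
    tr <- truth$replicates
    if (nrow(truth$artifacts)) {
      agg <- stats::aggregate(step ~ well, data = truth$artifacts,
                              FUN = function(s) paste(s, collapse = ","))
      tr$artifact_steps <- agg$step[match(tr$well, agg$well)]
      tr$artifact_steps[is.na(tr$artifact_steps)] <- ""
    } else {
      tr$artifact_steps <- ""
    }
    utils::write.table(tr, file.path(dir, "ground_truth_synthetic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(files)
}
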