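# Two-stage quality control:
#   1. step artifacts -- per-step area changes that run against the expected
#      migration trend AND sit in the extreme tail of a kernel density
#      estimate fitted to the condition's pooled deltas;
#   2. replicate screening -- technical replicates whose trajectory is
#      unusually far (Euclidean distance) from the others.
# Every flag is resolved by an accept/reject decision (policy or decision
# file) before analysis proceeds; nothing is destructive.

#' Fit a kernel density estimate to per-step area changes
#'
#' The estimator is `f(x) = (1/(n h)) * sum_i K((x - x_i)/h)` with kernel
#' `K` (Gaussian by default, Epanechnikov built in, others pluggable via
#' [register_plugin()]). With `bandwidth = "auto"` Silverman's rule
#' `h = 0.9 * min(sd, IQR/1.34) * n^(-1/5)` is used; data with zero spread
#' fall back to `h = 1e-3 * max(1, |mean|)` with a warning. At least two
#' points are required for automatic bandwidth selection; a fixed numeric
#' bandwidth permits a single point.
#'
#' @param x Numeric vector of deltas (finite).
#' @param kernel Kernel name registered in the `kde_kernel` plugin slot.
#' @param bandwidth `"auto"` or a positive number.
#' @return Object of class `cm_kde` with fields `points`, `bandwidth`,
#'   `kernel`. Evaluate it with [kde_density()] and [kde_cdf()].
#' @examples
#' k <- fit_kde(c(-1, 1), kernel = "gaussian", bandwidth = 1)
#' kde_density(k, 0) # dnorm(1) = 0.24197...
#' @export
fit_kde <- function(x, kernel = "gaussian", bandwidth = "auto") {
  x <- as.numeric(x)
  if (any(!is.finite(x)))
    cm_stop("deltas must be finite", "cm_value_error")
  get_plugin("kde_kernel", kernel) # existence check
  if (identical(bandwidth, "auto")) {
    if (length(x) < 2L)
      cm_stop("automatic bandwidth needs at least 2 points", "cm_value_error")
    spread <- min(stats::sd(x), stats::IQR(x) / 1.34)
    if (spread > 0) {
      h <- 0.9 * spread * length(x)^(-1 / 5)
    } else {
      h <- 1e-3 * max(1, abs(mean(x)))
      cm_warn("zero spread in deltas; falling back to a nominal bandwidth")
    }
  } else {
    h <- check_number(bandwidth, "bandwidth")
    if (h <= 0) cm_stop("'bandwidth' must be positive", "cm_value_error")
    if (length(x) < 1L)
      cm_stop("need at least 1 point", "cm_value_error")
  }
  structure(list(points = x, bandwidth = h, kernel = kernel),
            class = "cm_kde")
}

#' @rdname fit_kde
#' @param kde A fitted `cm_kde`.
#' @param at Numeric vector of evaluation points.
#' @export
kde_density <- function(kde, at) {
  stopifnot(inherits(kde, "cm_kde"))
  K <- get_plugin("kde_kernel", kde$kernel)$density
  vapply(at, function(x0)
    mean(K((x0 - kde$points) / kde$bandwidth)) / kde$bandwidth, 0)
}

#' @rdname fit_kde
#' @details `kde_cdf()` uses the closed-form kernel CDF (exact, no numeric
#'   quadrature): `F(x) = mean_i K_cdf((x - x_i)/h)`.
#' @export
kde_cdf <- function(kde, at) {
  stopifnot(inherits(kde, "cm_kde"))
  Kcdf <- get_plugin("kde_kernel", kde$kernel)$cdf
  vapply(at, function(x0)
    mean(Kcdf((x0 - kde$points) / kde$bandwidth)), 0)
}

#' @export
print.cm_kde <- function(x, ...) {
  cat(sprintf("<kde> %s kernel, n = %d, h = %.6g\n", x$kernel,
              length(x$points), x$bandwidth))
  invisible(x)
}

#' Detect artifact time steps in a normalized trajectory
#'
#' A step is flagged as an artifact when both halves of the criterion hold:
#' (a) its delta runs against the expected migration trend (e.g. the
#' cell-free area grows in an open-area assay -- typically a segmentation or
#' imaging error), and (b) the delta lies in the extreme against-trend tail
#' of the reference KDE, i.e. its tail probability under the density is
#' below `alpha`. The direction test keeps ordinary noise from being
#' flagged; the tail test keeps small against-trend wobbles from being
#' flagged. The KDE is normally fitted on the deltas pooled across all
#' replicates of the condition (see [run_qc()]), which stabilizes the
#' density at typical replicate counts.
#'
#' @param ns A normalized series that has been through [orient_series()].
#' @param kde A [fit_kde()] result (the reference delta distribution).
#' @param alpha Tail mass defining "extreme" (default 0.05).
#' @param rule Outlier rule name in the `outlier_rule` plugin slot.
#' @return Data frame with one row per flagged step, sorted by `step`:
#'   columns `well`, `source_label`, `step` (1-based index into `deltas`,
#'   i.e. the step from point `step` to `step + 1`), `delta`,
#'   `density_at_delta`, `reason`.
#' @export
detect_step_artifacts <- function(ns, kde, alpha = 0.05, rule = "tail_mass") {
  stopifnot(inherits(ns, "normalized_series"))
  if (!inherits(kde, "cm_kde"))
    cm_stop("'kde' must be a fitted cm_kde (see fit_kde)", "cm_state_error")
  if (is.null(ns$assay_kind))
    cm_stop("series must be oriented first (see orient_series)",
            "cm_state_error")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    cm_stop("'alpha' must be in (0, 1)", "cm_value_error")
  direction <- if (ns$assay_kind == "open_area") 1 else -1
  extreme <- get_plugin("outlier_rule", rule)
  hit <- which(ns$against_trend &
                 vapply(ns$deltas, function(d)
                   isTRUE(extreme(kde, d, alpha, direction)), NA))
  data.frame(well = rep(ns$well, length(hit)),
             source_label = rep(ns$source_label, length(hit)),
             step = as.integer(hit),
             delta = ns$deltas[hit],
             density_at_delta = if (length(hit)) kde_density(kde, ns$deltas[hit]) else numeric(),
             reason = rep("against_trend_excess", length(hit)),
             stringsAsFactors = FALSE)
}

#' Apply the suggested correction for one artifact step
#'
#' The point terminating the flagged step is replaced by time-weighted
#' linear interpolation between its neighbours; when the flagged step is the
#' final one the terminal point is dropped instead. Deltas (and the
#' against-trend flags, if the series is oriented) are recomputed; the
#' pre-correction trajectory is kept in `$original` for audit. Correcting
#' the same step twice is an idempotent no-op with a warning. No other point
#' is ever modified.
#'
#' @param ns A normalized series.
#' @param step 1-based index into `ns$deltas` of the flagged step.
#' @return The corrected series.
#' @export
correct_artifact <- function(ns, step) {
  stopifnot(inherits(ns, "normalized_series"))
  n <- length(ns$normalized)
  step <- as.integer(step)
  if (length(step) != 1L || is.na(step) || step < 1L || step > n - 1L)
    cm_stop(sprintf("'step' must index a delta (1..%d)", n - 1L),
            "cm_value_error")
  if (step %in% ns$corrected_steps) {
    cm_warn(sprintf("step %d of %s [%s] already corrected; no-op",
                    step, ns$well, ns$source_label))
    return(ns)
  }
  if (is.null(ns$original))
    ns$original <- list(time = ns$time, normalized = ns$normalized)
  idx <- step + 1L # the point terminating the flagged step
  if (idx == n) {
    ns$time <- ns$time[-n]
    ns$normalized <- ns$normalized[-n]
  } else {
    t0 <- ns$time[idx - 1L]; t2 <- ns$time[idx + 1L]
    v0 <- ns$normalized[idx - 1L]; v2 <- ns$normalized[idx + 1L]
    ns$normalized[idx] <- v0 + (v2 - v0) * (ns$time[idx] - t0) / (t2 - t0)
  }
  ns$corrected_steps <- c(ns$corrected_steps, step)
  refresh_deltas(ns)
}

#' Screen technical replicates by trajectory distance
#'
#' Computes all pairwise distances between the replicates' normalized
#' trajectories (default metric Euclidean, over the time points the pair
#' shares exactly -- within `1e-9` relative tolerance; at least
#' `min_shared` shared points are required) and each replicate's mean
#' distance to the others. A replicate is flagged as divergent when its mean
#' distance exceeds `median + k_mad * MAD` of the mean distances (scaled
#' MAD, constant 1.4826) -- a robust rule that is not masked by the outlier
#' itself.
#'
#' @param series_list List of normalized series (one per replicate, >= 2).
#' @param metric Distance metric name in the `distance_metric` plugin slot.
#' @param k_mad Multiplier `k` in the `median + k * MAD` cutoff (default 3).
#' @param min_shared Minimum number of shared time points per pair.
#' @param condition Optional condition name carried into the report.
#' @return Object of class `replicate_distance_report`: `distance_matrix`
#'   (symmetric, zero diagonal, replicate wells as dimnames),
#'   `mean_distance`, `threshold`, `flagged` (character vector of wells),
#'   `condition`.
#' @export
replicate_distances <- function(series_list, metric = "euclidean", k_mad = 3,
                                min_shared = 3, condition = NA_character_) {
  if (length(series_list) < 2L)
    cm_stop("replicate screening needs at least 2 replicates", "cm_value_error")
  dist_fun <- get_plugin("distance_metric", metric)
  ids <- vapply(series_list, function(s) s$well, "")
  if (anyDuplicated(ids))
    ids <- paste(ids, vapply(series_list, function(s) s$source_label, ""),
                 sep = ":")
  n <- length(series_list)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- series_list[[i]]; b <- series_list[[j]]
      match_idx <- shared_times(a$time, b$time)
      if (nrow(match_idx) < min_shared)
        cm_stop(sprintf(
          "replicates %s and %s share only %d time point(s) (need >= %d)",
          ids[i], ids[j], nrow(match_idx), min_shared), "cm_grid_error")
      d <- dist_fun(a$normalized[match_idx$i], b$normalized[match_idx$j])
      D[i, j] <- D[j, i] <- d
    }
  }
  mean_dist <- rowSums(D) / (n - 1L)
  threshold <- stats::median(mean_dist) + k_mad * stats::mad(mean_dist)
  structure(list(condition = condition, distance_matrix = D,
                 mean_distance = mean_dist, threshold = threshold,
                 k_mad = k_mad, metric = metric,
                 flagged = ids[mean_dist > threshold]),
            class = "replicate_distance_report")
}

# indices of exactly-matching time values (1e-9 relative tolerance)
shared_times <- function(ta, tb) {
  tol <- 1e-9
  i <- j <- integer()
  for (k in seq_along(ta)) {
    hit <- which(abs(tb - ta[k]) <= tol * pmax(1, abs(ta[k])))
    if (length(hit)) { i <- c(i, k); j <- c(j, hit[1L]) }
  }
  data.frame(i = i, j = j)
}

#' @export
print.replicate_distance_report <- function(x, ...) {
  cat(sprintf("<replicate_distance_report> %s: %d replicates (%s)\n",
              x$condition, nrow(x$distance_matrix), x$metric))
  cat(sprintf("  mean distances: %s; cutoff %.4g\n",
              paste(sprintf("%.4g", x$mean_distance), collapse = ", "),
              x$threshold))
  cat(sprintf("  flagged: %s\n",
              if (length(x$flagged)) paste(x$flagged, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Resolve accept/reject decisions for QC flags
#'
#' Replaces the interactive accept/reject dialog of a GUI workflow: every
#' flag gets exactly one decision, either from a blanket policy
#' (`"accept_all"` / `"reject_all"`) or, under policy `"ask"`, from a
#' decision table (data frame or TSV file with columns `flag_id`,
#' `action`). Decision-table entries override the policy for their flag.
#' Under `"ask"`, any flag without an entry is an error listing the
#' unresolved ids.
#'
#' @param flags Data frame with a `flag_id` column (as produced by
#'   [run_qc()]).
#' @param policy `"accept_all"`, `"reject_all"` or `"ask"`.
#' @param decisions Optional decision table (data frame) or path to a TSV
#'   with columns `flag_id` and `action` (`accept` or `reject`).
#' @return `flags` with columns `action` (`"accept"`/`"reject"`) and
#'   `provenance` (`"config_policy"`/`"decision_file"`) appended.
#' @export
resolve_decisions <- function(flags,
                              policy = c("accept_all", "reject_all", "ask"),
                              decisions = NULL) {
  policy <- match.arg(policy)
  if (is.character(decisions) && length(decisions) == 1L)
    decisions <- utils::read.delim(decisions, stringsAsFactors = FALSE)
  if (!is.null(decisions)) {
    if (!all(c("flag_id", "action") %in% names(decisions)))
      cm_stop("decision table needs columns 'flag_id' and 'action'",
              "cm_format_error")
    bad <- setdiff(unique(decisions$action), c("accept", "reject"))
    if (length(bad))
      cm_stop(sprintf("invalid decision action(s): %s",
                      paste(bad, collapse = ", ")), "cm_format_error")
  }
  if (nrow(flags) == 0L) {
    flags$action <- character()
    flags$provenance <- character()
    return(flags)
  }
  idx <- if (is.null(decisions)) rep(NA_integer_, nrow(flags))
         else match(flags$flag_id, decisions$flag_id)
  action <- ifelse(is.na(idx),
                   switch(policy, accept_all = "accept",
                          reject_all = "reject", ask = NA_character_),
                   decisions$action[idx])
  if (anyNA(action))
    cm_stop(sprintf("unresolved QC flag(s) under policy 'ask': %s",
                    paste(flags$flag_id[is.na(action)], collapse = ", ")),
            "cm_resolution_error")
  flags$action <- action
  flags$provenance <- ifelse(is.na(idx), "config_policy", "decision_file")
  flags
}

# pointwise mean of normalized values over the series of one well, on the
# exact common time grid -- the replicate trajectory used downstream
combine_well_series <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  if (length(series_list) == 1L) return(series_list[[1L]])
  grid <- series_list[[1L]]$time
  for (s in series_list[-1L]) {
    m <- shared_times(grid, s$time)
    grid <- grid[m$i]
  }
  if (length(grid) < 3L)
    cm_stop(sprintf("series of well %s share only %d time point(s)",
                    series_list[[1L]]$well, length(grid)), "cm_grid_error")
  vals <- vapply(series_list, function(s) {
    m <- shared_times(grid, s$time)
    s$normalized[m$j]
  }, numeric(length(grid)))
  out <- series_list[[1L]]
  out$time <- grid
  out$normalized <- rowMeans(vals)
  out$source_label <- "combined"
  refresh_deltas(out)
}

#' Run both quality-control stages on a loaded experiment
#'
#' Pipeline: normalize and orient every series; per condition, fit a KDE to
#' the pooled per-step deltas (or per series with `pool = "replicate"`) and
#' flag artifact steps with [detect_step_artifacts()]; resolve and apply
#' accepted step corrections; combine multiple series per well (pointwise
#' mean on the common grid); screen replicates per condition with
#' [replicate_distances()]; resolve replicate flags, an accepted flag
#' excluding the replicate from velocity analysis (never from the archive).
#'
#' Flag ids are `step:<well>:<label>:<step>` and
#' `replicate:<condition>:<well>`.
#'
#' @param loaded A [loaded_experiment()].
#' @param alpha Tail mass for the artifact criterion (default 0.05).
#' @param k_mad Replicate-outlier cutoff multiplier (default 3).
#' @param kernel,bandwidth Passed to [fit_kde()].
#' @param metric Distance metric for replicate screening.
#' @param policy,decisions Passed to [resolve_decisions()].
#' @param pool `"condition"` (default) fits one KDE per condition on pooled
#'   deltas; `"replicate"` fits one per series.
#' @return Object of class `qc_report`: `normalized` (per-series, after
#'   accepted corrections), `replicates` (per-well combined series),
#'   `step_flags`, `replicate_flags`, `qc_log` (every flag with its
#'   decision), `excluded_wells`, `params`.
#' @export
run_qc <- function(loaded, alpha = 0.05, k_mad = 3, kernel = "gaussian",
                   bandwidth = "auto", metric = "euclidean",
                   policy = c("accept_all", "reject_all", "ask"),
                   decisions = NULL, pool = c("condition", "replicate")) {
  stopifnot(inherits(loaded, "loaded_experiment"))
  policy <- match.arg(policy)
  pool <- match.arg(pool)
  exp <- loaded$experiment
  owner <- assigned_wells(exp)
  with_data <- unique(vapply(loaded$series, `[[`, "", "well"))
  no_data <- setdiff(names(owner), with_data)
  if (length(no_data))
    cm_stop(sprintf("assigned well(s) with no data series: %s",
                    paste(sort(no_data), collapse = ", ")),
            "cm_validation_error")

  normalized <- lapply(order_series(loaded$series), function(ts) {
    kind <- exp$conditions[[owner[[ts$well]]]]$assay_kind
    orient_series(normalize_series(ts), kind)
  })
  names(normalized) <- vapply(normalized, function(s)
    paste(s$well, s$source_label, sep = ":"), "")

  # stage 1: artifact steps against a pooled (or per-series) delta KDE
  step_flags <- list()
  for (cond in exp$conditions) {
    members <- normalized[vapply(normalized, function(s)
      s$well %in% cond$wells, NA)]
    if (!length(members)) next
    cond_kde <- if (pool == "condition")
      fit_kde(unlist(lapply(members, `[[`, "deltas")), kernel, bandwidth)
    else NULL
    for (s in members) {
      kde <- cond_kde %||% fit_kde(s$deltas, kernel, bandwidth)
      fl <- detect_step_artifacts(s, kde, alpha = alpha)
      if (nrow(fl)) {
        fl$condition <- cond$name
        step_flags[[length(step_flags) + 1L]] <- fl
      }
    }
  }
  step_flags <- if (length(step_flags)) do.call(rbind, step_flags)
  else data.frame(well = character(), source_label = character(),
                  step = integer(), delta = numeric(),
                  density_at_delta = numeric(), reason = character(),
                  condition = character(), stringsAsFactors = FALSE)
  step_flags$flag_id <- if (nrow(step_flags))
    sprintf("step:%s:%s:%d", step_flags$well, step_flags$source_label,
            step_flags$step) else character()
  step_flags <- resolve_decisions(step_flags, policy, decisions)

  accepted <- step_flags[step_flags$action == "accept", , drop = FALSE]
  if (nrow(accepted)) {
    for (k in seq_len(nrow(accepted))) {
      key <- paste(accepted$well[k], accepted$source_label[k], sep = ":")
      normalized[[key]] <- correct_artifact(normalized[[key]],
                                            accepted$step[k])
    }
  }

  # stage 2: replicate screening on the per-well combined trajectories
  replicates <- list()
  replicate_flags <- list()
  distance_reports <- list()
  for (cond in exp$conditions) {
    combined <- lapply(cond$wells, function(w) {
      combine_well_series(unname(normalized[vapply(normalized, function(s)
        s$well == w, NA)]))
    })
    names(combined) <- cond$wells
    replicates[cond$wells] <- combined
    if (length(combined) >= 2L) {
      rep_report <- replicate_distances(combined, metric = metric,
                                        k_mad = k_mad,
                                        condition = cond$name)
      distance_reports[[cond$name]] <- rep_report
      if (length(rep_report$flagged))
        replicate_flags[[length(replicate_flags) + 1L]] <- data.frame(
          condition = cond$name, well = rep_report$flagged,
          mean_distance = rep_report$mean_distance[rep_report$flagged],
          threshold = rep_report$threshold, stringsAsFactors = FALSE)
    }
  }
  replicate_flags <- if (length(replicate_flags))
    do.call(rbind, replicate_flags)
  else data.frame(condition = character(), well = character(),
                  mean_distance = numeric(), threshold = numeric(),
                  stringsAsFactors = FALSE)
  replicate_flags$flag_id <- if (nrow(replicate_flags))
    sprintf("replicate:%s:%s", replicate_flags$condition,
            replicate_flags$well) else character()
  replicate_flags <- resolve_decisions(replicate_flags, policy, decisions)
  excluded <- replicate_flags$well[replicate_flags$action == "accept"]

  qc_log <- rbind(
    if (nrow(step_flags)) data.frame(
      flag_id = step_flags$flag_id, type = "step_artifact",
      condition = step_flags$condition, well = step_flags$well,
      source_label = step_flags$source_label, step = step_flags$step,
      value = step_flags$delta, reason = step_flags$reason,
      action = step_flags$action, provenance = step_flags$provenance,
      stringsAsFactors = FALSE),
    if (nrow(replicate_flags)) data.frame(
      flag_id = replicate_flags$flag_id, type = "divergent_replicate",
      condition = replicate_flags$condition, well = replicate_flags$well,
      source_label = NA_character_, step = NA_integer_,
      value = replicate_flags$mean_distance, reason = "distance_outlier",
      action = replicate_flags$action,
      provenance = replicate_flags$provenance, stringsAsFactors = FALSE))
  if (is.null(qc_log))
    qc_log <- data.frame(flag_id = character(), type = character(),
                         condition = character(), well = character(),
                         source_label = character(), step = integer(),
                         value = numeric(), reason = character(),
                         action = character(), provenance = character(),
                         stringsAsFactors = FALSE)

  structure(list(normalized = normalized, replicates = replicates,
                 step_flags = step_flags, replicate_flags = replicate_flags,
                 distance_reports = distance_reports, qc_log = qc_log,
                 excluded_wells = as.character(excluded),
                 params = list(alpha = alpha, k_mad = k_mad, kernel = kernel,
                               bandwidth = bandwidth, metric = metric,
                               policy = policy, pool = pool)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d step flag(s), %d replicate flag(s), %d well(s) excluded\n",
              nrow(x$step_flags), nrow(x$replicate_flags),
              length(x$excluded_wells)))
  invisible(x)
}

#' Write the QC log as TSV
#'
#' One row per flag with all artifact / divergent-replicate fields and the
#' decision taken.
#'
#' @param qc A [run_qc()] result.
#' @param path Output file.
#' @export
write_qc_log <- function(qc, path) {
  stopifnot(inherits(qc, "qc_report"))
  utils::write.table(qc$qc_log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
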