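# Velocity estimation and condition comparison.
#
# Migration velocity of one technical replicate is the ordinary
# least-squares slope of normalized area (percent of t0) on time; a
# condition's velocity is the median slope over its replicates. Conditions
# are compared pairwise on their replicate slope lists with the
# Mann-Whitney U test, with Bonferroni or Benjamini-Hochberg correction
# over the pairs tested.

#' Fit the migration velocity of one replicate
#'
#' Ordinary least squares of normalized area on time. The velocity is the
#' signed slope in percent of t0 area per time unit (negative when an open
#' cell-free area closes). `r_squared = 1 - SS_res/SS_tot`; for a
#' zero-variance response it is defined as 1 when all residuals vanish
#' (a perfectly flat trajectory) and 0 otherwise.
#'
#' @param ns A normalized series (at least 3 points after QC, non-constant
#'   time).
#' @return Object of class `replicate_fit`: `well`, `slope`, `intercept`,
#'   `r_squared`, `std_error` (OLS standard error of the slope),
#'   `n_points`.
#' @examples
#' ts <- well_series("A1", "s", 0:2, c(200, 180, 160))
#' fit_replicate(normalize_series(ts)) # slope -10, R^2 = 1
#' @export
fit_replicate <- function(ns) {
  stopifnot(inherits(ns, "normalized_series"))
  t <- ns$time; y <- ns$normalized
  if (length(t) < 3L)
    cm_stop("regression needs at least 3 points", "cm_value_error")
  if (stats::var(t) == 0)
    cm_stop("time values have zero variance", "cm_value_error")
  fit <- stats::lm(y ~ t)
  coefs <- stats::coef(fit)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res < 1e-12) 1 else 0
  } else max(0, min(1, 1 - ss_res / ss_tot))
  se <- sqrt(ss_res / (length(t) - 2L) / sum((t - mean(t))^2))
  structure(list(well = ns$well, slope = unname(coefs[2L]),
                 intercept = unname(coefs[1L]), r_squared = r2,
                 std_error = se, n_points = length(t)),
            class = "replicate_fit")
}

#' @export
print.replicate_fit <- function(x, ...) {
  cat(sprintf("<replicate_fit> %s: slope %.4g %%/unit (R^2 %.4g, n %d)\n",
              x$well, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Aggregate replicate fits into a condition velocity
#'
#' The condition's migration velocity is the median of its replicate
#' slopes; with an even replicate count the mean of the two central values,
#' as usual.
#'
#' @param fits Non-empty list of [fit_replicate()] results.
#' @param condition Optional condition name.
#' @return Object of class `condition_result` with `condition`, `fits`,
#'   `slopes` and `median_velocity`.
#' @export
condition_velocity <- function(fits, condition = NA_character_) {
  if (!length(fits))
    cm_stop("no replicate fits supplied", "cm_value_error")
  stopifnot(all(vapply(fits, inherits, NA, "replicate_fit")))
  slopes <- vapply(fits, `[[`, 0, "slope")
  structure(list(condition = condition, fits = fits, slopes = slopes,
                 median_velocity = stats::median(slopes)),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result> %s: median velocity %.4g %%/unit over %d replicate(s)\n",
              x$condition, x$median_velocity, length(x$fits)))
  invisible(x)
}

#' Mann-Whitney U test for two independent samples
#'
#' Rank-based two-sided test of a location difference. `U` is computed from
#' the rank sum of the first sample, with midranks for ties. The exact
#' p-value enumerates all `choose(n_a + n_b, n_a)` assignments of the
#' pooled values to the two groups (used when `mode = "exact"`, or under
#' `"auto"` when `n_a + n_b <= 12` and there are no ties); otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used. The two-sided p-value is `min(1, 2 * one-sided)`.
#'
#' @param a,b Numeric samples (non-empty; a warning is given below 3
#'   observations per group, where the test has essentially no power).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return List with `u` (the U statistic of sample `a`, in
#'   `[0, n_a * n_b]`), `p` (two-sided), and `method` used.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p # 0.1
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    cm_stop("both samples must be non-empty", "cm_value_error")
  if (any(!is.finite(c(a, b))))
    cm_stop("samples must be finite", "cm_value_error")
  if (min(length(a), length(b)) < 3L)
    cm_warn("fewer than 3 observations in a group; the test has little power")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  use_exact <- mode == "exact" || (mode == "auto" && n <= 12L && !ties)
  if (use_exact) {
    sets <- utils::combn(n, na)
    us <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p_le <- mean(us <= u + eps)
    p_ge <- mean(us >= u - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tc <- table(pooled)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tc^3 - tc) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      cc <- sign(z) * 0.5 # continuity correction toward the mean
      z <- (z - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  list(u = u, p = p, method = method)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up false
#' discovery rate control, applied over the tests actually performed.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @param method `"bonferroni"`, `"benjamini_hochberg"` (alias `"bh"`), or
#'   any name registered in the `correction_method` plugin slot.
#' @return Adjusted p-values in the input order, clipped to (0, 1].
#' @examples
#' adjust_pvalues(c(0.01, 0.04), "bonferroni") # 0.02 0.08
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "benjamini_hochberg")) {
  if (!is.numeric(p) || !length(p) || any(!is.finite(p)) ||
      any(p <= 0) || any(p > 1))
    cm_stop("p-values must lie in (0, 1]", "cm_value_error")
  method <- if (identical(method, "bh")) "benjamini_hochberg"
            else method[1L]
  get_plugin("correction_method", method)(p)
}

#' Compare conditions pairwise on their replicate velocities
#'
#' For every unordered pair of selected conditions, the replicate slope
#' lists are compared with [mann_whitney_u()]; the raw p-values are then
#' adjusted over the `choose(k, 2)` pairs actually tested, and significance
#' is called at `p_adjusted < alpha`.
#'
#' @param results List of [condition_velocity()] results (named or carrying
#'   condition names).
#' @param selection Character vector of condition names to compare (default
#'   all, >= 2).
#' @param method Correction method, see [adjust_pvalues()].
#' @param alpha Significance level for the adjusted p-values (default 0.05).
#' @param mode Test mode, see [mann_whitney_u()].
#' @return Data frame of class `pairwise_comparisons` with one row per
#'   pair: `condition_a`, `condition_b`, `u_statistic`, `p_raw`,
#'   `p_adjusted`, `significant`; attributes `method` and `alpha`.
#' @export
compare_conditions <- function(results, selection = NULL,
                               method = c("bonferroni", "benjamini_hochberg"),
                               alpha = 0.05,
                               mode = c("auto", "exact", "normal_approx")) {
  method <- if (identical(method, "bh")) "benjamini_hochberg" else method[1L]
  mode <- match.arg(mode)
  nm <- vapply(results, `[[`, "", "condition")
  if (!is.null(names(results)) && all(nzchar(names(results))))
    nm <- names(results)
  names(results) <- nm
  if (is.null(selection)) selection <- nm
  unknown <- setdiff(selection, nm)
  if (length(unknown))
    cm_stop(sprintf("unknown condition(s): %s",
                    paste(unknown, collapse = ", ")), "cm_lookup_error")
  if (length(selection) < 2L)
    cm_stop("need at least 2 conditions to compare", "cm_value_error")
  pairs <- utils::combn(selection, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- results[[pairs[1L, k]]]$slopes
    b <- results[[pairs[2L, k]]]$slopes
    mw <- mann_whitney_u(a, b, mode = mode)
    data.frame(condition_a = pairs[1L, k], condition_b = pairs[2L, k],
               u_statistic = mw$u, p_raw = mw$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_raw, method)
  out$significant <- out$p_adjusted < alpha
  structure(out, method = method, alpha = alpha,
            class = c("pairwise_comparisons", "data.frame"))
}
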