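test_that("replicate fits agree with closed-form least squares", {
  ns <- normalize_series(well_series("A1", "s", 0:2, c(200, 180, 160)))
  fit <- fit_replicate(ns)
  expect_equal(fit$slope, -10)
  expect_equal(fit$intercept, 100)
  expect_equal(fit$r_squared, 1)

  flat <- fit_replicate(normalize_series(
    well_series("A1", "s", 0:3, c(70, 70, 70, 70))))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 1) # zero-variance response, zero residuals

  hand <- fit_replicate(normalize_series(
    well_series("A1", "s", 0:2, c(100, 95, 84))))
  expect_equal(hand$slope, -8) # sum((t-tbar)(y-ybar))/sum((t-tbar)^2)
  o <- oracle_ols(0:2, c(100, 95, 84))
  expect_equal(hand$r_squared, o$r2, tolerance = 1e-12)

  set.seed(21)
  for (k in 1:50) {
    n <- sample(3:25, 1)
    t <- sort(sample(0:100, n))
    y <- stats::runif(1, 50, 150) + stats::runif(1, -10, 5) * t +
      stats::rnorm(n, 0, 3)
    y <- pmax(y, 1)
    if (stats::var(y) == 0) next # clipped flat: no closed-form R^2
    y <- 100 * y / y[1]
    fit <- fit_replicate(normalize_series(well_series("A1", "s", t, y)))
    o <- oracle_ols(t, y)
    expect_equal(fit$slope, o$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, o$r2, tolerance = 1e-9)
    # R^2 is invariant under affine rescaling of time
    resc <- fit_replicate(normalize_series(
      well_series("A1", "s", 2.5 * t + 1, y)))
    expect_equal(resc$r_squared, fit$r_squared, tolerance = 1e-9)
  }

  expect_error(fit_replicate(normalize_series(
    well_series("A1", "s", 0:1, c(100, 90)))), class = "cm_value_error")
})

test_that("condition velocity is the median slope with the even-count rule", {
  mk <- function(s) structure(list(well = "A1", slope = s, intercept = 100,
                                   r_squared = 1, std_error = 0,
                                   n_points = 5), class = "replicate_fit")
  expect_equal(condition_velocity(lapply(c(-8, -10, -12), mk))$median_velocity, -10)
  expect_equal(condition_velocity(lapply(c(-8, -10), mk))$median_velocity, -9)
  expect_equal(condition_velocity(list(mk(-10)))$median_velocity, -10)
  expect_error(condition_velocity(list()), class = "cm_value_error")
})

test_that("Mann-Whitney U matches enumeration and the u_a + u_b identity", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1) # both extreme orderings among C(6,3)=20

  suppressWarnings(tie <- mann_whitney_u(c(5, 5), c(5, 5)))
  expect_equal(tie$u, 2) # n_a n_b / 2
  expect_equal(tie$p, 1)

  inter <- mann_whitney_u(c(1, 3, 5), c(2, 4, 6), mode = "exact")
  o <- oracle_mann_whitney(c(1, 3, 5), c(2, 4, 6))
  expect_equal(inter$u, o$u)
  expect_equal(inter$p, o$p, tolerance = 1e-12)

  set.seed(22)
  for (k in 1:30) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    vals <- sample(1:40, na + nb) # no ties
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    suppressWarnings(r <- mann_whitney_u(a, b, mode = "exact"))
    ub <- suppressWarnings(mann_whitney_u(b, a, mode = "exact"))$u
    expect_equal(r$u + ub, na * nb)
    o <- oracle_mann_whitney(a, b)
    expect_equal(r$p, o$p, tolerance = 1e-12)
    # wilcox.test is an independent implementation of the same exact test
    w <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(r$u, unname(w$statistic))
    expect_equal(r$p, w$p.value, tolerance = 1e-12)
  }
})

test_that("the normal approximation agrees with the reference under ties", {
  set.seed(23)
  for (k in 1:20) {
    na <- sample(5:15, 1); nb <- sample(5:15, 1)
    a <- sample(1:8, na, replace = TRUE)
    b <- sample(2:9, nb, replace = TRUE)
    mine <- mann_whitney_u(a, b, mode = "normal_approx")
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = TRUE))
    expect_equal(mine$u, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  }
  # auto switches to the approximation for large or tied samples
  expect_identical(mann_whitney_u(1:10, 11:17)$method, "normal_approx")
  suppressWarnings(
    expect_identical(mann_whitney_u(c(1, 1), c(2, 3))$method, "normal_approx"))
  expect_identical(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$method, "exact")
  expect_error(mann_whitney_u(numeric(0), 1:3), class = "cm_value_error")
})

test_that("p-value adjustment matches hand values and the step-up oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "benjamini_hochberg"),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(0.03, "benjamini_hochberg"), 0.03)

  set.seed(24)
  for (k in 1:200) {
    p <- stats::runif(sample(1:12, 1))
    bh <- adjust_pvalues(p, "benjamini_hochberg")
    bon <- adjust_pvalues(p, "bonferroni")
    expect_equal(bh, oracle_bh(p), tolerance = 1e-12)
    expect_equal(bon, pmin(1, length(p) * p))
    expect_true(all(bon >= bh - 1e-12)) # Bonferroni dominates BH
    expect_true(all(bh > 0 & bh <= 1))
    # permutation equivariance
    perm <- sample(seq_along(p))
    expect_equal(adjust_pvalues(p[perm], "benjamini_hochberg"), bh[perm])
  }
  expect_error(adjust_pvalues(c(0.5, 0), "bonferroni"), class = "cm_value_error")
  expect_error(adjust_pvalues(1.2, "bonferroni"), class = "cm_value_error")
})

test_that("condition comparison tests every selected pair and adjusts over them", {
  mkres <- function(name, slopes) condition_velocity(
    lapply(slopes, function(s)
      structure(list(well = "A1", slope = s, intercept = 100, r_squared = 1,
                     std_error = 0, n_points = 5),
                class = "replicate_fit")), name)
  res <- list(mkres("a", c(-10, -11, -9, -10.5)),
              mkres("b", c(-2, -2.5, -1.8, -2.2)),
              mkres("c", c(-6, -6.2, -5.9, -6.1)))
  cmp <- compare_conditions(res, method = "benjamini_hochberg")
  expect_equal(nrow(cmp), 3) # C(3,2)
  expect_true(all(cmp$p_adjusted >= cmp$p_raw - 1e-12))

  same <- compare_conditions(list(mkres("x", c(-5, -6, -7)),
                                  mkres("y", c(-5, -6, -7))))
  expect_equal(same$p_adjusted, 1)
  expect_false(same$significant)

  expect_error(compare_conditions(res, selection = c("a", "zz")),
               class = "cm_lookup_error")
  expect_error(compare_conditions(res, selection = "a"),
               class = "cm_value_error")
})

test_that("well-separated conditions come out significant after correction", {
  set.seed(25)
  spec <- sim_spec(list(list(name = "A", true_slope = -10, n_replicates = 6),
                        list(name = "B", true_slope = -2, n_replicates = 6),
                        list(name = "C", true_slope = -9.5, n_replicates = 6)),
                   noise_sd = 0.5, seed = 77)
  ana <- analyze_experiment(simulate_experiment(spec),
                            correction = "benjamini_hochberg")
  cmp <- ana$comparisons
  ab <- cmp[cmp$condition_a == "A" & cmp$condition_b == "B", ]
  expect_true(ab$significant)
  expect_lt(ab$p_adjusted, 0.05)
})

test_that("the plugin registry registers, rejects duplicates, and serves lookups", {
  expect_error(register_plugin("distance_metric", "euclidean", identity),
               class = "cm_conflict_error")
  expect_error(register_plugin("frobnicator", "x", identity),
               class = "cm_lookup_error")
  expect_error(get_plugin("distance_metric", "no_such"),
               class = "cm_lookup_error")

  name <- paste0("chebyshev_", sample.int(1e6, 1))
  register_plugin("distance_metric", name, function(x, y) max(abs(x - y)))
  expect_true(name %in% list_plugins("distance_metric"))
  mk <- function(vals, well) normalize_series(
    well_series(well, "s", seq_along(vals) - 1, vals))
  rep <- replicate_distances(list(mk(c(100, 90, 80), "A1"),
                                  mk(c(100, 86, 77), "A2")), metric = name)
  expect_equal(unname(rep$distance_matrix[1, 2]), 4)
})
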