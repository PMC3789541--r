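# Shared fixtures and independent oracles, built in code at test time.

# small two-condition experiment on a 96-well plate
make_experiment <- function() {
  exp <- experiment("exp1", project = "demo", date = as.Date("2024-03-01"),
                    plate = plate_format(8, 12))
  exp <- add_condition(exp, condition("ctrl", cell_line = "MCF7",
                                      treatment = "vehicle", dose = 0,
                                      assay_kind = "open_area",
                                      extra = list(passage = "12"),
                                      wells = c("A1", "A2", "A3")))
  exp <- add_condition(exp, condition("drug", cell_line = "MCF7",
                                      treatment = "cpdX", dose = 10,
                                      dose_unit = "uM",
                                      wells = c("B1", "B2", "B3")))
  exp
}

# experiment + deterministic linear series for every assigned well
make_loaded <- function(exp = make_experiment(), n_points = 5) {
  t <- seq(0, n_points - 1)
  loaded <- loaded_experiment(exp)
  slope_of <- c(ctrl = -10, drug = -2)
  for (cond in exp$conditions) {
    for (w in cond$wells) {
      area <- 1000 * (1 + slope_of[[cond$name]] / 100 * t)
      loaded <- attach_series(loaded, well_series(w, "pos1", t, area))
    }
  }
  loaded
}

# randomly shaped valid experiment, for round-trip property tests
random_experiment <- function() {
  rows <- sample(2:8, 1)
  cols <- sample(2:12, 1)
  exp <- experiment(paste0("exp-", sample.int(1e6, 1)),
                    project = sample(c("", "projA", "projB"), 1),
                    date = as.Date("2024-01-01") + sample.int(300, 1),
                    plate = plate_format(rows, cols),
                    time_unit = sample(c("h", "min"), 1),
                    area_unit = sample(c("um2", "pixel2"), 1))
  all_wells <- as.vector(outer(LETTERS[seq_len(rows)], seq_len(cols), paste0))
  all_wells <- sample(all_wells)
  n_cond <- sample(1:3, 1)
  taken <- 0
  for (k in seq_len(n_cond)) {
    n_wells <- sample(1:3, 1)
    extra <- if (stats::runif(1) < 0.5)
      stats::setNames(as.list(paste0("v", 1:2)), paste0("key", 1:2))
    else list()
    exp <- add_condition(exp, condition(
      paste0("cond", k), cell_line = paste0("line", k),
      treatment = paste0("trt", k), dose = round(stats::runif(1, 0, 50), 3),
      dose_unit = "uM",
      assay_kind = sample(c("open_area", "covered_area"), 1),
      extra = extra, wells = all_wells[taken + seq_len(n_wells)]))
    taken <- taken + n_wells
  }
  exp
}

expect_experiment_equal <- function(a, b) {
  expect_identical(a$identifier, b$identifier)
  expect_identical(a$project, b$project)
  expect_identical(a$date, b$date)
  expect_identical(unclass(a$plate), unclass(b$plate))
  expect_identical(a$time_unit, b$time_unit)
  expect_identical(a$area_unit, b$area_unit)
  expect_identical(names(a$conditions), names(b$conditions))
  for (nm in names(a$conditions))
    expect_identical(unclass(a$conditions[[nm]]),
                     unclass(b$conditions[[nm]]))
}

# --- independent oracles ------------------------------------------------

# Mann-Whitney oracle: U by direct pair counting, p by enumerating all
# group assignments (counting path is independent of the rank-sum path
# used by the implementation)
oracle_mann_whitney <- function(a, b) {
  count_u <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- count_u(a, b)
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  us <- apply(idx, 2, function(i) count_u(pooled[i], pooled[-i]))
  eps <- 1e-9
  p <- min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
  list(u = u_obs, p = p)
}

# brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * p[ord][i:m] / (i:m))), 0)
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# closed-form OLS on (t, y)
oracle_ols <- function(t, y) {
  slope <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  intercept <- mean(y) - slope * mean(t)
  res <- y - intercept - slope * t
  list(slope = slope, intercept = intercept,
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
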