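test_that("well files parse, skip one header row, and sort by time", {
  f <- write_tsv_lines(c("0\t200", "1\t180", "2\t160"))
  ts <- read_well_file(f, "A1", "pos1")
  expect_equal(ts$time, c(0, 1, 2))
  expect_equal(ts$area, c(200, 180, 160))

  f <- write_tsv_lines(c("time\tarea", "0\t200", "4\t100"))
  ts <- read_well_file(f, "A1")
  expect_length(ts$time, 2)

  f <- write_tsv_lines(c("2\t160", "0\t200", "1\t180"))
  ts <- read_well_file(f, "A1")
  expect_equal(ts$area, c(200, 180, 160))
})

test_that("well files with bad content fail with informative format errors", {
  expect_error(read_well_file(write_tsv_lines(c("0\t200", "0\t190")), "A1"),
               "duplicate", class = "cm_format_error")
  expect_error(read_well_file(write_tsv_lines("0\t200"), "A1"),
               class = "cm_format_error")
  expect_error(read_well_file(write_tsv_lines(c("0\t200", "1\tx2")), "A1"),
               "line 2", class = "cm_format_error")
  expect_error(read_well_file(write_tsv_lines(c("0\t200", "1,5\t180")), "A1"),
               class = "cm_format_error") # decimal comma is not locale-guessed
  expect_error(read_well_file(write_tsv_lines(c("0\t200", "1\t-5")), "A1"),
               class = "cm_format_error")
})

test_that("parsing is insensitive to CRLF endings and trailing blank lines", {
  set.seed(7)
  for (k in 1:10) {
    n <- sample(3:8, 1)
    t <- sort(sample(0:50, n))
    a <- round(stats::runif(n, 50, 500), 3)
    body <- sprintf("%g\t%g", t, a)
    plain <- write_tsv_lines(body)
    crlf <- tempfile(fileext = ".tsv")
    writeLines(paste0(body, "\r"), crlf, sep = "\n")
    trailing <- write_tsv_lines(c(body, "", ""))
    base <- read_well_file(plain, "A1")
    for (f in c(crlf, trailing)) {
      alt <- read_well_file(f, "A1")
      expect_equal(alt$time, base$time)
      expect_equal(alt$area, base$area)
    }
    # serialize -> re-parse is the identity
    rt <- write_tsv_lines(c("time\tarea",
                            sprintf("%.17g\t%.17g", base$time, base$area)))
    again <- read_well_file(rt, "A1")
    expect_identical(again$time, base$time)
    expect_identical(again$area, base$area)
  }
})

test_that("series attach to assigned wells only, labels distinguish them", {
  loaded <- loaded_experiment(make_experiment())
  ts1 <- well_series("A1", "pos1", 0:2, c(100, 90, 80))
  ts2 <- well_series("A1", "pos2", 0:2, c(100, 88, 79))
  loaded <- attach_series(loaded, ts1)
  loaded <- attach_series(loaded, ts2)
  expect_length(loaded$series, 2)
  expect_error(attach_series(loaded, well_series("E7", "pos1", 0:2, c(1, 2, 3))),
               class = "cm_assignment_error")
  expect_error(attach_series(loaded, ts1), class = "cm_conflict_error")
})

test_that("full-experiment XML embeds every point and round-trips exactly", {
  loaded <- make_loaded()
  doc <- export_experiment_xml(loaded)
  expect_length(xml2::xml_find_all(doc, "//series"), 6)
  expect_length(xml2::xml_find_all(doc, "//point"), 30)

  # irrational-ish values must survive bit-for-bit
  exp <- make_experiment()
  l2 <- loaded_experiment(exp)
  for (cond in exp$conditions)
    for (w in cond$wells)
      l2 <- attach_series(l2, well_series(w, "pos1", c(0, 1 / 3, exp(1)),
                                          c(pi * 100, 250.123456789012, 199.9)))
  f <- tempfile(fileext = ".xml")
  export_experiment_xml(l2, f)
  back <- import_experiment_xml(f)
  expect_identical(names(back$series), names(l2$series))
  for (key in names(l2$series)) {
    expect_identical(back$series[[key]]$time, l2$series[[key]]$time)
    expect_identical(back$series[[key]]$area, l2$series[[key]]$area)
  }
  expect_experiment_equal(l2$experiment, back$experiment)
})

test_that("experiment XML export/import reject inconsistent documents", {
  loaded <- make_loaded()
  # a well with no data is named in the error
  short <- loaded_experiment(make_experiment())
  short$series <- loaded$series[-1]
  expect_error(export_experiment_xml(short), "A1",
               class = "cm_validation_error")

  f <- tempfile(fileext = ".xml")
  export_experiment_xml(loaded, f)
  txt <- readLines(f)
  trunc <- tempfile(fileext = ".xml")
  writeLines(txt[1:(length(txt) %/% 2)], trunc)
  expect_error(import_experiment_xml(trunc), class = "cm_parse_error")

  # series for a well no condition owns
  bad <- gsub('well="A1"', 'well="H12"', paste(txt, collapse = "\n"))
  expect_error(import_experiment_xml(bad), class = "cm_assignment_error")
})
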