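test_that("recordings round-trip through delimited text bitwise", {
  withr::with_seed(5, {
    m <- matrix(rnorm(300, sd = 0.8), ncol = 3)
  })
  rec <- gait_recording(m, "s1", "left", "on")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, "s1", "left", "on")
  expect_identical(unname(back$samples), unname(rec$samples))
  expect_equal(n_samples(back), 100L)
})

test_that("reader preserves row count and order for 3- and 4-column files", {
  path <- withr::local_tempfile(fileext = ".csv")
  n <- 5760
  withr::with_seed(2, m <- matrix(round(rnorm(3 * n, sd = 0.5), 6), ncol = 3))
  writeLines(apply(m, 1, paste, collapse = ","), path)
  rec <- read_recording(path, "s1", "right", "off", header = FALSE)
  expect_equal(n_samples(rec), n)
  expect_equal(unname(rec$samples[c(1, n), ]), unname(m[c(1, n), ]))
  # leading timestamp column at exactly fs is validated then discarded
  path4 <- withr::local_tempfile(fileext = ".tsv")
  ts <- (seq_len(n) - 1) / 32
  writeLines(paste(ts, m[, 1], m[, 2], m[, 3], sep = "\t"), path4)
  rec4 <- read_recording(path4, "s1", "right", "off", header = FALSE)
  expect_equal(unname(rec4$samples), unname(rec$samples))
})

test_that("timestamps inconsistent with fs are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  ts <- (0:99) / 25            # implies 25 Hz, not 32
  writeLines(paste(ts, 0.1, 0.2, 0.3, sep = ","), path)
  expect_error(read_recording(path, "s", "left", fs = 32, header = FALSE),
               "inconsistent with fs")
})

test_that("malformed rows are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.1,0.2,0.3", "0.1,0.2,oops", "0.1,0.2,0.3"), path)
  expect_error(read_recording(path, "s", "left", header = FALSE), "line 2")
  writeLines(c("0.1,0.2,0.3", "0.1,0.2"), path)
  expect_error(read_recording(path, "s", "left", header = FALSE), "line 2")
})

test_that("the +/- 8 g sensor range is enforced, never silently passed", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.1,0.2,0.3", "9.5,0.2,0.3"), path)
  expect_error(read_recording(path, "s", "left", header = FALSE),
               "8 g sensor range")
  expect_warning(
    rec <- read_recording(path, "s", "left", header = FALSE,
                          range_action = "clip"),
    "clipped")
  expect_equal(max(rec$samples), 8)
})

test_that("feature tables round-trip losslessly and refuse to be empty", {
  tab <- toy_feature_table(n_subjects = 2, windows_per_course = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab[1:17, ], path)
  expect_equal(length(readLines(path)), 18L)   # header + 17 rows
  back <- read_feature_table(path)
  expect_identical(names(back), names(tab))
  expect_equal(back[feature_names()], tab[1:17, feature_names()],
               ignore_attr = TRUE)
  expect_error(write_feature_table(tab[0, ], path), "empty")
})

test_that("cohort configs load recordings with metadata attached", {
  dir <- withr::local_tempdir()
  withr::with_seed(9, {
    for (f in c("a_on_left", "a_on_right")) {
      m <- matrix(rnorm(30), ncol = 3)
      utils::write.table(m, file.path(dir, paste0(f, ".csv")), sep = ",",
                         row.names = FALSE, col.names = FALSE)
    }
  })
  cfg <- list(fs = 32, recordings = list(
    list(path = "a_on_left.csv", subject_id = "a", knee = "left",
         state = "on"),
    list(path = "a_on_right.csv", subject_id = "a", knee = "right",
         state = "on")))
  yaml::write_yaml(cfg, file.path(dir, "cohort.yaml"))
  cohort <- read_cohort_config(file.path(dir, "cohort.yaml"))
  expect_s3_class(cohort, "gait_cohort")
  expect_equal(cohort$roster, "a")
  expect_equal(vapply(cohort$recordings, `[[`, character(1), "knee"),
               c("left", "right"))
})

test_that("cohort completeness validation flags missing courses", {
  withr::with_seed(3, m <- matrix(rnorm(30), ncol = 3))
  recs <- list(
    gait_recording(m, "a", "left", "on"),
    gait_recording(m, "a", "right", "on"),
    gait_recording(m, "a", "left", "off"),
    gait_recording(m, "a", "right", "off"))
  expect_true(validate_cohort(gait_cohort(recs)))
  expect_error(validate_cohort(gait_cohort(recs[1:3])), "4 expected")
})
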