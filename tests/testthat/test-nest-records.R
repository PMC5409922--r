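test_that("record parsing maps fields, sentinels and structures", {
  csv <- data.frame(
    year = c("2009", "2009", "2014"),
    date_found = c("2009-06-02", "2009-09-01", "2014-11-20"),
    date_destroyed = c("2009-06-03", "2009-09-04", "0"),
    stage = c("primary", "secondary", "secondary"),
    structure = c("building", "oak", ""))
  rec <- parse_nest_records(csv)
  expect_s3_class(rec, "nest_records")
  expect_equal(rec$stage, c("primary", "secondary", "secondary"))
  expect_equal(rec$structure_class, c("man_made", "natural", "unknown"))
  expect_equal(rec$tree_genus, c(NA, "oak", NA))
  # sentinel "0" destruction date: never destroyed
  expect_true(is.na(rec$date_destroyed[3]))
  expect_equal(rec$activity_at_destruction,
               c("active", "active", "not_destroyed"))
  expect_equal(nrow(attr(rec, "rejected")), 0)
})

test_that("tree genus implies a natural structure", {
  rec <- parse_nest_records(data.frame(
    year = "2009", date_found = "2009-06-01", date_destroyed = "2009-06-02",
    stage = "secondary", structure = c("pine")))
  expect_true(all(is.na(rec$tree_genus) |
                    rec$structure_class == "natural"))
})

test_that("header-only input yields an empty record set and empty tally", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("year,date_found,date_destroyed,stage", f)
  rec <- parse_nest_records(f)
  expect_equal(nrow(rec), 0)
  expect_equal(nrow(tally_yearly(rec)), 0)
})

test_that("malformed rows are rejected with row and field named", {
  csv <- data.frame(
    year = c("2009", "2009", "2009", "2009"),
    date_found = c("2009-06-02", "not-a-date", "2009-06-01", "2009-08-01"),
    date_destroyed = c("2009-06-03", "2009-06-05", "2009-06-09", "2009-07-01"),
    stage = c("primary", "primary", "tertiary", "primary"))
  rec <- parse_nest_records(csv)
  rej <- attr(rec, "rejected")
  expect_equal(nrow(rec), 1)
  expect_setequal(rej$row, c(2L, 3L, 4L))
  expect_equal(rej$field[rej$row == 2], "date_found")
  expect_equal(rej$field[rej$row == 3], "stage")
  # destruction before discovery is impossible
  expect_equal(rej$field[rej$row == 4], "date_destroyed")
  expect_error(parse_nest_records(csv, stop_on_error = TRUE), "rejected")
})

test_that("activity classification follows the calendar cut-off rules", {
  cut <- activity_cutoffs()
  expect_equal(classify_activity("primary", as.Date("2009-08-10"), cut),
               "inactive")
  expect_equal(classify_activity("primary", as.Date("2009-07-31"), cut),
               "active")
  expect_equal(classify_activity("secondary", as.Date("2009-11-20"), cut),
               "inactive")
  expect_equal(classify_activity("secondary", as.Date("2009-10-01"), cut),
               "active")
  expect_equal(classify_activity("unknown", as.Date("2009-11-15"), cut),
               "active")
  expect_equal(classify_activity("primary", as.Date(NA), cut),
               "not_destroyed")
})

test_that("later destruction never flips inactive back to active", {
  cut <- activity_cutoffs()
  for (stage in c("primary", "secondary", "unknown")) {
    dates <- as.Date("2010-01-01") + 0:364
    act <- classify_activity(rep(stage, length(dates)), dates, cut)
    numeric_state <- ifelse(act == "active", 1, 0)
    expect_true(all(diff(numeric_state) <= 0),
                info = paste("monotone for", stage))
  }
})

test_that("custom cut-offs shift the classification boundary", {
  late <- activity_cutoffs(primary = "08-31", secondary = "12-15")
  expect_equal(classify_activity("primary", as.Date("2009-08-10"), late),
               "active")
  expect_error(activity_cutoffs(primary = "12-01", secondary = "11-15"))
})

test_that("yearly tally equals a brute-force per-record count and is
           permutation invariant", {
  set.seed(42)
  for (rep in 1:5) {
    raw <- random_records(60)
    rec <- parse_nest_records(raw)
    got <- tally_yearly(rec)
    expect_equal(as.data.frame(got), oracle_tally(rec),
                 ignore_attr = TRUE)
    perm <- rec[sample(nrow(rec)), ]
    expect_equal(as.data.frame(tally_yearly(perm)), as.data.frame(got),
                 ignore_attr = TRUE)
  }
})

test_that("single record lands in exactly the matching cells", {
  rec <- parse_nest_records(data.frame(
    year = "2010", date_found = "2010-05-01", date_destroyed = "2010-05-03",
    stage = "primary"))
  counts <- tally_yearly(rec)
  expect_equal(counts$n_detected_total, 1)
  expect_equal(counts$n_primary, 1)
  expect_equal(counts$n_active_primary_destroyed, 1)
  expect_equal(counts$n_secondary + counts$n_unclassified +
                 counts$n_active_secondary_destroyed, 0)
})

test_that("colony counting rule matches the published row", {
  counts <- andernos_counts()
  expect_equal(detected_colonies(counts), c(4, 27, 63, 40, 62, 76, 85, 99))
})

test_that("colony count falls back to total detections for
           stage-unrecorded years", {
  c07 <- make_counts(2007, 4, 0, 0, 4, 0, 1)
  expect_equal(detected_colonies(c07), 4)
  c09 <- make_counts(2009, 83, 38, 45, 0, 18, 14)
  expect_equal(detected_colonies(c09), 63)
  zero <- make_counts(2020, 0, 0, 0, 0, 0, 0)
  expect_equal(detected_colonies(zero), 0)
  mixed <- make_counts(2012, 10, 4, 3, 3, 2, 1)
  expect_warning(n <- detected_colonies(mixed), "unclassified")
  expect_equal(n, 2 + 3 + 3)
})

test_that("counts validation rejects inconsistent tables", {
  bad <- make_counts(2009, 83, 38, 45, 0, 18, 14)
  bad$n_detected_total <- 80
  expect_error(validate_yearly_counts(bad), "sum")
  bad2 <- make_counts(2009, 83, 38, 45, 0, 40, 14)
  expect_error(validate_yearly_counts(bad2), "primaries")
})

test_that("yearly counts round-trip through CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  counts <- andernos_counts()
  write_yearly_counts(counts, f)
  expect_equal(as.data.frame(read_yearly_counts(f)),
               as.data.frame(counts), ignore_attr = TRUE)
})
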