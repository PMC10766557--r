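test_that("report table round-trips losslessly through write and read", {
  cfg <- synthetic_config(n_reports_per_year = 40, dup_fraction = 0.05, seed = 11)
  r <- generate_reports(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report_table(r, path)
  r2 <- read_report_table(path)
  for (col in setdiff(names(r), c("drugs", "aes"))) {
    expect_equal(r2[[col]], r[[col]], info = col)
  }
  # sets compare as sets
  expect_equal(lapply(r2$drugs, sort), lapply(r$drugs, sort))
  expect_equal(lapply(r2$aes, sort), lapply(r$aes, sort))
})

test_that("report table writer emits one row per report with joined sets", {
  r <- mk_reports("c1", "2020-04-01", drugs = list(c("d1", "d2", "d3")),
                  aes = list(c("ae1", "ae2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report_table(r, path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  expect_match(lines[2], "d1;d2;d3")
  expect_match(lines[2], "ae1;ae2")
  # empty collection -> header only
  write_report_table(ae_reports(), path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_report_table(path)), 0L)
})

test_that("reader maps unknown sentinels and rejects malformed fields", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "caseid\tversion\tdate\tcountry\tage_years\tsex\tweight_kg\tqualification\tseverity\tdrugs\taes"
  writeLines(c(hdr, "c1\t1\t2020-05-01\tUS\tNA\tU\tNA\tNA\t000000\td1\tae1"), path)
  r <- read_report_table(path)
  expect_true(is.na(r$sex))
  expect_true(is.na(r$age))
  expect_true(is.na(r$qualification))
  writeLines(c(hdr, "c1\t1\t2020-05-01\tUS\t4\tF\t70\t1\t000000\td1;;d2\tae1"), path)
  expect_error(read_report_table(path), "row")
  writeLines(c("caseid\tdate", "c1\t2020-05-01"), path)
  expect_error(read_report_table(path), "aes")
})

test_that("deduplication keeps the latest report per case and is idempotent", {
  r <- mk_reports(c("case1", "case1", "case2"),
                  c("2020-01-01", "2020-05-01", "2020-02-01"))
  d <- deduplicate_reports(r)
  expect_equal(nrow(d), 2L)
  expect_equal(d$date[d$case_id == "case1"], as.Date("2020-05-01"))
  # date ties broken by version, then by input order (later row wins)
  r2 <- mk_reports(c("c", "c", "c"), rep("2020-03-01", 3), version = c(2L, 1L, 1L),
                   aes = list("first", "mid", "last"))
  expect_equal(deduplicate_reports(r2)$aes[[1]], "first")
  r3 <- mk_reports(c("c", "c"), rep("2020-03-01", 2), version = c(1L, 1L),
                   aes = list("early", "late"))
  expect_equal(deduplicate_reports(r3)$aes[[1]], "late")
  # unique ids -> identity as a set; idempotence
  expect_equal(deduplicate_reports(d), d)
})

test_that("synthetic duplicates are removed exactly", {
  cfg <- synthetic_config(n_reports_per_year = 500, dup_fraction = 0.05, seed = 3)
  r <- generate_reports(cfg)
  n_dup <- sum(duplicated(r$case_id))
  expect_equal(n_dup, floor(0.05 * 500 * 8))
  d <- deduplicate_reports(r)
  expect_equal(nrow(d), nrow(r) - n_dup)
  # the survivor of each duplicated pair is the later submission
  dup_ids <- unique(r$case_id[duplicated(r$case_id)])
  for (id in dup_ids[1:5]) {
    expect_equal(d$date[d$case_id == id], max(r$date[r$case_id == id]))
  }
})

test_that("cohort filtering respects window boundaries and unknown handling", {
  r <- mk_reports(
    c("a", "b", "c", "d", "e", "f"),
    c("2020-03-11", "2020-09-30", "2020-03-10", "2020-10-01", "2020-06-01", "2020-06-01"),
    country = c("US", "US", "US", "US", "FR", "US"),
    qualification = c(1L, 2L, 1L, 1L, 1L, 5L)
  )
  kept <- filter_cohort(r, cohort_spec(years = 2020))
  expect_setequal(kept$case_id, c("a", "b"))  # boundary dates kept, outside dropped
  # consumers excluded under the professional default; unknown qualification too
  r2 <- mk_reports(c("u1", "u2"), rep("2020-05-01", 2),
                   qualification = c(NA_integer_, 3L))
  expect_equal(filter_cohort(r2, cohort_spec(years = 2020))$case_id, "u2")
  # unknown sex kept unless a sex filter is set
  r3 <- mk_reports(c("s1", "s2"), rep("2020-05-01", 2), sex = c(NA_integer_, 2L))
  expect_equal(nrow(filter_cohort(r3, cohort_spec(years = 2020))), 2L)
  expect_equal(filter_cohort(r3, cohort_spec(years = 2020, sex = 2))$case_id, "s2")
  # idempotence
  spec <- cohort_spec(years = 2020)
  expect_equal(filter_cohort(filter_cohort(r, spec), spec), filter_cohort(r, spec))
})

test_that("counting obeys the partition identity and clause monotonicity", {
  cfg <- synthetic_config(n_reports_per_year = 300, seed = 5)
  r <- generate_reports(cfg)
  total_2019 <- count_reports(r, year = 2019)
  expect_equal(
    count_reports(r, ae = "ae30", year = 2019) +
      count_reports(r, ae = "ae30", year = 2019, ae_negated = TRUE),
    total_2019
  )
  expect_equal(count_reports(ae_reports(), year = 2019), 0L)
  expect_error(count_reports(r), "clause")
  # adding clauses never increases the count
  n1 <- count_reports(r, ae = "ae30")
  n2 <- count_reports(r, ae = "ae30", year = 2019)
  n3 <- count_reports(r, ae = "ae30", year = 2019, drug = "drug10")
  expect_true(n1 >= n2 && n2 >= n3)
})

test_that("yearly proportion matches direct division and handles extremes", {
  r <- mk_yearly_reports(rep(100L, 8), c(0L, rep(10L, 6), 29L))
  expect_equal(yearly_proportion(r, "ae1", 2020), 0.29)
  expect_equal(yearly_proportion(r, "ae1", 2013), 0)
  expect_equal(yearly_proportion(r, "absent", 2019), 0)
  expect_equal(yearly_proportion(r, "bg", 2019), 1)
  expect_error(yearly_proportion(r, "ae1", 2012), "no reports")
})
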