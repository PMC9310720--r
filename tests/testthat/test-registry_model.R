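write_fixture_csvs <- function(dir, overrides = list()) {
  dir.create(dir, showWarnings = FALSE)
  base <- list(
    persons = c("person_id,sex,birth_date,municipality,death_date",
                "P1,F,1980-05-01,M01,", "P2,M,1970-01-15,M02,2018-03-01",
                "P3,F,1995-12-31,M01,"),
    residency = c("person_id,start,end", "P1,2010-01-01,2019-01-01",
                  "P2,2010-01-01,2019-01-01", "P3,2010-01-01,2019-01-01"),
    diagnoses = c("person_id,date,icd10,care_level",
                  "P1,2013-02-01,F329,primary",
                  "P2,2014-06-10,F331,psychiatric_outpatient"),
    dispensations = c("person_id,date,atc,tablets,daily_dose_mg",
                      "P1,2013-02-05,N06AB10,100,"),
    procedures = c("person_id,date,procedure,care_level",
                   "P1,2013-03-01,psychotherapy,primary"),
    visits = c("person_id,date,care_level,physician",
               "P1,2013-02-01,primary,TRUE", "P2,2012-01-01,other,FALSE"),
    stays = c("person_id,admission_date,discharge_date,ward",
              "P2,2014-06-01,2014-06-11,psychiatric"),
    workloss = c("person_id,start,end,kind,extent",
                 "P1,2013-02-10,2013-03-20,sick_leave,1")
  )
  base[names(overrides)] <- overrides
  for (nm in names(base)) writeLines(base[[nm]], file.path(dir, paste0(nm, ".csv")))
  dir
}

test_that("conforming files load with parsed dates and typed columns", {
  dir <- write_fixture_csvs(withr::local_tempdir())
  tabs <- load_tables(dir)
  expect_equal(nrow(tabs$persons), 3L)
  expect_s3_class(tabs$persons$birth_date, "Date")
  expect_equal(tabs$persons[person_id == "P2", death_date], D("2018-03-01"))
  expect_type(tabs$dispensations$tablets, "integer")
  expect_true(is.na(tabs$dispensations$daily_dose_mg[1]))
  expect_identical(tabs$visits$physician, c(TRUE, FALSE))
})

test_that("schema violations are named in strict mode and dropped when lenient", {
  dir <- write_fixture_csvs(withr::local_tempdir(), list(
    diagnoses = c("person_id,date,icd10,care_level",
                  "P1,2013-02-01,32F,primary",
                  "P2,2014-06-10,F331,psychiatric_outpatient")))
  expect_error(load_tables(dir), "icd10 must match")
  expect_message(tabs <- load_tables(dir, schema_strict = FALSE), "dropped 1")
  expect_equal(nrow(tabs$diagnoses), 1L)

  dir2 <- write_fixture_csvs(withr::local_tempdir(), list(
    stays = c("person_id,admission_date,discharge_date,ward",
              "P2,2014-06-11,2014-06-01,psychiatric")))
  expect_message(tabs2 <- load_tables(dir2, schema_strict = FALSE),
                 "dropped 1.*discharge before admission")
  expect_equal(nrow(tabs2$stays), 0L)

  dir3 <- write_fixture_csvs(withr::local_tempdir(), list(
    persons = c("person_id,sex,birth_date", "P1,F,1980-05-01")))
  expect_error(load_tables(dir3), "missing column.*municipality")
})

test_that("events outside residency raise a warning, not an error", {
  dir <- write_fixture_csvs(withr::local_tempdir(), list(
    residency = c("person_id,start,end", "P1,2014-01-01,2019-01-01",
                  "P2,2010-01-01,2019-01-01", "P3,2010-01-01,2019-01-01")))
  expect_warning(load_tables(dir), "outside any residency")
})

test_that("write/load round trip is byte-identical for conforming files", {
  sim <- generate_registry(sim_config(seed = 11, n_persons = 300))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_tables(sim$tables, d1)
  tabs <- load_tables(d1)
  write_tables(tabs, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("depressive events collect the allowed event classes in date order", {
  cb <- default_codebook()
  tabs <- mk_tables(
    diagnoses = dx_row("P1", "2013-02-01"),
    dispensations = rbind(rx_row("P1", "2013-03-01"),
                          rx_row("P1", "2013-01-15", atc = "C07AB02")),  # not AD
    procedures = proc_row("P1", "2013-04-01", "ECT", "psychiatric_inpatient"))
  ev <- depressive_events(tabs, cb, "P1")
  expect_equal(ev$event_class, c("diagnosis", "dispensation", "procedure"))
  expect_true(!is.unsorted(ev$date))
  expect_equal(depressive_events(tabs, cb, "nobody")[, .N], 0L)
})

test_that("quetiapine counts as add-on only above the dose threshold", {
  cb <- default_codebook()
  tabs <- mk_tables(dispensations = rbind(
    rx_row("P1", "2013-01-01", atc = "N05AH04", dose = 100),   # at threshold: out
    rx_row("P1", "2013-02-01", atc = "N05AH04", dose = 150),   # above: in
    rx_row("P1", "2013-03-01", atc = "N05AH04", dose = NA),    # unknown: out
    rx_row("P1", "2013-04-01", atc = "N05AN01")))              # lithium: in
  ev <- depressive_events(tabs, cb, "P1")
  expect_equal(as.character(ev$date), c("2013-02-01", "2013-04-01"))
})

test_that("depressive events are stable under row shuffling of the inputs", {
  cb <- default_codebook()
  set.seed(4)
  dx <- rbindlist(lapply(1:6, function(i)
    dx_row("P1", D("2013-01-01") + i * 30)))
  rx <- rbindlist(lapply(1:4, function(i) rx_row("P1", D("2013-02-01") + i * 45)))
  t1 <- mk_tables(diagnoses = dx, dispensations = rx)
  t2 <- mk_tables(diagnoses = dx[sample(.N)], dispensations = rx[sample(.N)])
  expect_equal(depressive_events(t1, cb), depressive_events(t2, cb))
})
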