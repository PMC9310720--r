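cb <- default_codebook()
iw <- c("2012-01-01", "2019-01-01")

test_that("incidence requires the first-ever MDD diagnosis inside the window", {
  tabs <- mk_tables(
    persons = rbind(person_row("A"), person_row("B"), person_row("C")),
    residency = rbind(residency_row("A"), residency_row("B"), residency_row("C")),
    diagnoses = rbind(
      dx_row("A", "2011-06-01"), dx_row("A", "2013-04-01", "F331"),  # first-ever 2011
      dx_row("B", "2012-01-01", "F331"),                             # boundary: in
      dx_row("C", "2014-07-01")))
  cases <- find_incident_cases(tabs, cb, iw)
  expect_setequal(cases$person_id, c("B", "C"))
  expect_equal(cases[person_id == "B", index_date], D("2012-01-01"))
})

test_that("same-day care levels resolve psychiatric > primary > other", {
  tabs <- mk_tables(
    persons = person_row("A"),
    residency = residency_row("A"),
    diagnoses = rbind(dx_row("A", "2013-01-10", care = "primary"),
                      dx_row("A", "2013-01-10", "F331", "psychiatric_outpatient")))
  cases <- find_incident_cases(tabs, cb, iw)
  expect_equal(nrow(cases), 1L)
  expect_equal(cases$care_level_at_index, "psychiatric")
})

test_that("history exclusions and the residency washout drop the right cases", {
  tabs <- mk_tables(
    persons = rbind(person_row("A"), person_row("B"), person_row("C")),
    residency = rbind(residency_row("A"), residency_row("B"),
                      residency_row("C", start = "2013-09-23")),  # 100 days before index
    diagnoses = rbind(
      dx_row("A", "2014-01-01"), dx_row("A", "2012-01-01", "F31", "psychiatric_outpatient"),
      dx_row("B", "2014-01-01"), dx_row("B", "2014-06-01", "F200", "psychiatric_outpatient"),
      dx_row("C", "2014-01-01")))
  cases <- apply_exclusions(find_incident_cases(tabs, cb, iw), tabs, cb)
  # A: bipolar 2 years before index -> excluded; B: psychosis after -> retained;
  # C: only 100 days of residency before index -> excluded
  expect_equal(cases$person_id, "B")
})

test_that("control eligibility enforces the any-time and at-index rules", {
  tabs <- mk_tables(
    persons = rbind(person_row("X"), person_row("Y", death = "2012-06-01"),
                    person_row("Z")),
    residency = rbind(residency_row("X"), residency_row("Y"), residency_row("Z")),
    dispensations = rx_row("X", "2017-03-01"))  # AD years after candidate index
  idx <- D("2013-01-01")
  expect_false(eligible_control("X", idx, tabs, cb))  # any-time AD rule
  expect_false(eligible_control("Y", idx, tabs, cb))  # dead before index
  expect_true(eligible_control("Z", idx, tabs, cb))
})

test_that("matching samples the stratum with replacement and flags empty strata", {
  tabs <- mk_tables(
    persons = rbind(person_row("case1", birth = "1980-01-01", muni = "M01"),
                    person_row("case2", birth = "1981-01-01", muni = "M01"),
                    person_row("case3", birth = "1980-01-01", muni = "M09"),
                    person_row("ctl", birth = "1979-06-01", muni = "M01")),
    residency = rbind(residency_row("case1"), residency_row("case2"),
                      residency_row("case3"), residency_row("ctl")),
    diagnoses = rbind(dx_row("case1", "2013-02-01"), dx_row("case2", "2013-03-01"),
                      dx_row("case3", "2013-04-01")))
  cases <- apply_exclusions(find_incident_cases(tabs, cb, iw), tabs, cb)
  pairs <- match_controls(cases, tabs, cb, seed = 2)
  # the single eligible control serves both M01 cases; the M09 case is unmatched
  expect_equal(pairs[case_id %in% c("case1", "case2"), control_id], c("ctl", "ctl"))
  expect_true(is.na(pairs[case_id == "case3", control_id]))
  expect_identical(pairs, match_controls(cases, tabs, cb, seed = 2))
})

test_that("censoring takes the earliest terminating event with the tie-break order", {
  tabs <- mk_tables(
    persons = rbind(person_row("A"), person_row("B", death = "2014-07-20"),
                    person_row("Tie", death = "2014-02-19")),
    residency = rbind(residency_row("A"), residency_row("B"),
                      residency_row("Tie", end = "2014-02-20")),  # emigration day = death day
    diagnoses = rbind(dx_row("A", "2014-01-01"), dx_row("B", "2014-01-01"),
                      dx_row("Tie", "2014-01-01"),
                      dx_row("B", "2014-04-01", "F200", "psychiatric_outpatient")))
  cen <- censor(c("A", "B", "Tie"), rep(D("2014-01-01"), 3), tabs, cb)
  expect_equal(cen[person_id == "A", .(follow_up_end, reason)],
               data.table(follow_up_end = D("2018-12-31"), reason = "end_of_data"))
  # exclusion dx (day 90) precedes death (day 200)
  expect_equal(cen[person_id == "B", .(follow_up_end, reason)],
               data.table(follow_up_end = D("2014-04-01"), reason = "exclusion_dx"))
  # death and emigration on the same day: death wins
  expect_equal(cen[person_id == "Tie", reason], "death")
})

test_that("matched pairs are balanced on synthetic data", {
  out <- generate_registry(sim_config(seed = 17, n_persons = 8000))
  coh <- build_cohort(out$tables, cb, seed = 17)
  m <- coh$members
  expect_equal(anyDuplicated(m[group == "mdd", person_id]), 0L)
  expect_true(all(m$follow_up_end >= m$index_date))
  # sex identical within pairs; age caliper respected
  w <- data.table::dcast(m, pair_id ~ group, value.var = c("sex", "age_at_index"))
  w <- w[!is.na(sex_control)]
  expect_gt(nrow(w), 200L)
  expect_true(all(w$sex_control == w$sex_mdd))
  expect_true(all(abs(w$age_at_index_control - w$age_at_index_mdd) <= 2L))
  match_rate <- mean(!is.na(coh$pairs$control_id))
  expect_gte(match_rate, 0.95)
  expect_lte(match_rate, 1)
})
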