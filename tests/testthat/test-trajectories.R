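cb <- default_codebook()

test_that("supply windows apply the 25% adherence buffer with ceiling rounding", {
  sw <- supply_window(D("2013-01-01"), c(100L, 30L, 1L))
  expect_equal(as.numeric(sw$cover_end - sw$cover_start), c(125, 38, 2))
})

test_that("drug coverage and procedure months flag treatment on the calendar grid", {
  m <- member_row("P1", "2014-03-15", "2018-12-31")
  # fill on the last day of the index month: 125 covered days (Mar 31..Aug 2)
  # touch six calendar months, 0..5
  tabs <- mk_tables(dispensations = rx_row("P1", "2014-03-31", tablets = 100L),
                    procedures = proc_row("P1", "2014-05-01", "ECT",
                                          "psychiatric_inpatient"))
  grid <- monthly_exposure(m, tabs, cb)
  ad <- grid[therapy == "AD" & treated == TRUE, m]
  expect_equal(ad, 0:5)
  expect_equal(grid[therapy == "ECT" & treated == TRUE, m], 2L)
})

test_that("months after censoring are not at risk", {
  m <- member_row("P1", "2014-03-15", "2014-08-10")  # censored in month 5
  tabs <- mk_tables()
  grid <- monthly_exposure(m, tabs, cb)
  ar <- grid[therapy == "AD", .(m, at_risk)]
  expect_true(all(ar[m <= 5, at_risk]))
  expect_false(any(ar[m >= 6, at_risk]))
})

test_that("proportion series are consistent: cumulative dominates point and is monotone", {
  out <- generate_registry(sim_config(seed = 19, n_persons = 3000))
  coh <- build_cohort(out$tables, cb, seed = 19)
  grid <- monthly_exposure(coh$members, out$tables, cb)
  pt <- proportion_series(grid, "point")
  # same (at-risk) denominator: ever-treated dominates currently-treated
  cm_ar <- proportion_series(grid, "cumulative", denominator = "at_risk")
  j <- merge(pt, cm_ar, by = c("therapy", "m"), suffixes = c(".pt", ".cum"))
  expect_true(all(j$proportion.cum >= j$proportion.pt - 1e-12))
  # default fixed-cohort denominator: monotone by construction
  cm <- proportion_series(grid, "cumulative")
  for (th in unique(cm$therapy))
    expect_true(!is.unsorted(cm[therapy == th][order(m), proportion] + 1e-12),
                info = th)
  # an all-zero grid yields zero proportions
  g0 <- data.table::copy(grid)[, treated := FALSE]
  expect_true(all(proportion_series(g0, "point")$proportion == 0))
})

test_that("comorbidity lookback admits five years and anchors at month -12", {
  m <- member_row("P1", "2014-06-15", "2018-12-31")
  mk_dx <- function(date) mk_tables(diagnoses = dx_row("P1", date, "F411"))
  # 4 years pre-index: qualifies, counted from the grid start
  s <- comorbidity_series(m, mk_dx("2010-06-20"), cb, conditions = "anxiety")
  expect_true(all(s$proportion == 1))
  # 6 years pre-index: never qualifies
  s <- comorbidity_series(m, mk_dx("2008-06-20"), cb, conditions = "anxiety")
  expect_true(all(s$proportion == 0))
  # diagnosis in month +3 counts from month 3 on
  s <- comorbidity_series(m, mk_dx("2014-09-02"), cb, conditions = "anxiety")
  expect_equal(s[proportion > 0, min(m)], 3L)
  expect_true(all(s[m >= 3, proportion] == 1))
})

test_that("drug exposure agrees with a day-grid coverage oracle on random streams", {
  set.seed(23)
  for (rep in 1:200) {
    index <- D("2014-01-01") + sample(0:365, 1)
    n_fill <- sample(1:6, 1)
    fills <- sort(sample(-380:380, n_fill))
    tablets <- sample(c(10L, 28L, 100L), n_fill, replace = TRUE)
    m <- member_row("P1", index, "2018-12-31")
    tabs <- mk_tables(dispensations = rbindlist(lapply(seq_len(n_fill), function(i)
      rx_row("P1", index + fills[i], tablets = tablets[i]))))
    grid <- monthly_exposure(m, tabs, cb)[therapy == "AD"]
    # oracle: mark every covered calendar day, then test month membership
    covered <- unlist(lapply(seq_len(n_fill), function(i) {
      s <- as.numeric(index + fills[i])
      s:(s + ceiling(tablets[i] * 1.25) - 1)
    }))
    for (mm in -12:12) {
      w <- mddburden:::month_window(index, mm)
      want <- any(covered >= as.numeric(w$start) & covered < as.numeric(w$end))
      expect_equal(grid[m == mm, treated], want,
                   info = paste("rep", rep, "month", mm))
    }
  }
})

test_that("a single default fill covers a bounded number of months", {
  set.seed(31)
  for (rep in 1:50) {
    index <- D("2014-01-01") + sample(0:365, 1)
    m <- member_row("P1", index, "2018-12-31")
    tabs <- mk_tables(dispensations = rx_row("P1", index + sample(-300:300, 1),
                                             tablets = 100L))
    grid <- monthly_exposure(m, tabs, cb)[therapy == "AD"]
    n_months <- grid[treated == TRUE, .N]
    expect_gte(n_months, 1L)
    expect_lte(n_months, ceiling(125 / 28) + 1L)
  }
})

test_that("pre-index psychiatric comorbidity climbs toward index on ramped data", {
  out <- generate_registry(sim_config(seed = 29, n_persons = 6000))
  coh <- build_cohort(out$tables, cb, seed = 29)
  cs <- comorbidity_series(coh$members, out$tables, cb,
                           conditions = c("anxiety", "stress"))
  for (cond in c("anxiety", "stress")) {
    p12 <- cs[condition == cond & m == -12, proportion]
    p0 <- cs[condition == cond & m == 0, proportion]
    ratio <- p0 / p12
    expect_gt(ratio, 1.5)
    expect_lt(ratio, 3.5)
  }
})
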