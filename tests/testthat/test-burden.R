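test_that("the weighted annualized mean matches hand-computed closed forms", {
  est <- weighted_annual_mean(c(2, 4))
  expect_equal(est$estimate, 3)
  expect_equal(est$se, sqrt(2) / 2)
  expect_equal(c(est$ci_low, est$ci_high), 3 + c(-1, 1) * 1.959964 * sqrt(2) / 2,
               tolerance = 1e-9)

  # exact proportional fit: zero variance
  w <- c(0.3, 0.7, 1)
  est <- weighted_annual_mean(5 * w, w)
  expect_equal(est$estimate, 5)
  expect_equal(est$se, 0)

  # unit weights: the estimate is the sample mean and the robust SE equals
  # sqrt((n-1)/n) * sd / sqrt(n)
  set.seed(8)
  x <- rpois(50, 4)
  est <- weighted_annual_mean(x)
  expect_equal(est$estimate, mean(x))
  expect_equal(est$se, sqrt(49 / 50) * sd(x) / sqrt(50))

  expect_error(weighted_annual_mean(c(1, 2), c(1, 0)))
})

test_that("the ratio estimator is unbiased for Poisson outcomes with fractional weights", {
  for (s in 1:3) {
    set.seed(s)
    w <- runif(10000, 0.2, 1)
    x <- rpois(10000, 5 * w)
    est <- weighted_annual_mean(x, w)
    expect_lt(abs(est$estimate - 5), 3 * est$se)
  }
})

test_that("burden ratios reproduce printed-table arithmetic with half-up rounding", {
  expect_equal(burden_ratio(7.90, 2.48), 3.2)
  expect_equal(burden_ratio(5.68, 2.58), 2.2)
  expect_equal(burden_ratio(3, 3), 1.0)
  expect_equal(burden_ratio(2.25, 1, digits = 1), 2.3)  # ties away from zero
  expect_error(burden_ratio(1, 0), "zero")
})

test_that("bed days split across month boundaries by interval overlap", {
  m <- member_row("P1", "2014-03-10", "2018-12-31")
  tabs <- mk_tables(stays = data.table(person_id = "P1",
                                       admission_date = D("2014-03-22"),
                                       discharge_date = D("2014-04-06"),
                                       ward = "non_psychiatric"))
  hru <- monthly_hru(m, tabs)
  bd <- hru[measure == "bed_days" & level == "total"]
  expect_equal(bd[m == 0, mean], 10)  # Mar 22..31
  expect_equal(bd[m == 1, mean], 5)   # Apr 1..5
  # non-physician visits are not counted
  tabs2 <- mk_tables(visits = data.table(person_id = "P1", date = D("2014-03-12"),
                                         care_level = "primary", physician = FALSE))
  expect_true(all(monthly_hru(m, tabs2)[measure == "visits", mean] == 0))
})

test_that("bed-day levels decompose exactly into the total", {
  out <- generate_registry(sim_config(seed = 37, n_persons = 4000))
  coh <- build_cohort(out$tables, default_codebook(), seed = 37)
  hru <- monthly_hru(coh$members, out$tables)
  wide <- data.table::dcast(hru[measure == "bed_days"], group + m ~ level,
                            value.var = "mean")
  expect_equal(wide$psychiatric + wide$non_psychiatric, wide$total, tolerance = 1e-12)
})

test_that("work-loss rules: 14-day threshold, extent scaling, age restriction", {
  mk_wl <- function(start, end, kind = "sick_leave", extent = 1)
    mk_tables(workloss = data.table(person_id = "P1", start = D(start),
                                    end = D(end), kind = kind, extent = extent))
  m <- member_row("P1", "2014-03-10", "2018-12-31")
  # 13-day spell: dropped
  wl <- monthly_workloss(m, mk_wl("2014-03-05", "2014-03-18"))
  expect_true(all(wl$mean == 0))
  # 30-day spell at extent 0.5 fully inside the index month
  wl <- monthly_workloss(m, mk_wl("2014-03-01", "2014-03-31", extent = 0.5))
  expect_equal(wl[level == "sick_leave" & m == 0, mean], 15)
  # short disability-pension spells are kept (threshold applies to sick leave)
  wl <- monthly_workloss(m, mk_wl("2014-03-01", "2014-03-11", "disability_pension"))
  expect_equal(wl[level == "disability_pension" & m == 0, mean], 10)
  # a 19-year-old contributes to no denominator
  young <- member_row("P1", "2014-03-10", "2018-12-31", age = 19L)
  expect_equal(nrow(monthly_workloss(young, mk_wl("2014-03-01", "2014-03-31"))), 0L)
})

test_that("monthly series and the annual estimator count the same events", {
  # index on the first of a month in a non-leap year: calendar months 0..11
  # cover exactly the post-index day window
  m <- member_row("P1", "2013-01-01", "2018-12-31")
  vis <- data.table(person_id = "P1",
                    date = D("2013-01-01") + c(3, 40, 100, 200, 360),
                    care_level = "primary", physician = TRUE)
  tabs <- mk_tables(visits = vis)
  hru <- monthly_hru(m, tabs, months = 0:11)
  po <- annual_outcomes(m, tabs)
  expect_equal(sum(hru[measure == "visits" & level == "total", mean]),
               po[outcome == "visits_total" & window == "post", x])
})

test_that("annual weights reflect followed fractions of the post window", {
  m <- rbind(member_row("P1", "2014-01-01", "2018-12-31"),
             member_row("P2", "2014-01-01", "2014-06-30", reason = "death"))
  po <- annual_outcomes(m, mk_tables())
  expect_equal(po[person_id == "P1" & window == "post", w][1], 1)
  expect_equal(po[person_id == "P2" & window == "post", w][1],
               (as.numeric(D("2014-06-30") - D("2014-01-01")) + 1) / 365)
  expect_true(all(po[window == "pre", w] == 1))
})
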