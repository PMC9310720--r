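far_end <- D("2012-01-01") + 5000

test_that("hand-traced event streams produce the traced episode boundaries", {
  # single diagnosis, nothing after: degenerate zero-length episode, gap-closed
  ep <- build_episodes(ev_stream(0, "diagnosis"), data_end = far_end)
  expect_equal(ep[, .(ordinal, s = as.numeric(start_date - D("2012-01-01")),
                      e = as.numeric(end_date - D("2012-01-01")), closure)],
               data.table(ordinal = 1L, s = 0, e = 0, closure = "gap"))

  # dx d0; AD fill d200 of 100 tablets: gap 200 keeps ongoing, dispensation
  # closes the episode and extends it by the supply to d300
  ep <- build_episodes(ev_stream(c(0, 200), c("diagnosis", "dispensation"),
                                 c(NA, 100L)), data_end = far_end)
  expect_equal(as.numeric(ep$end_date - D("2012-01-01")), 300)
  expect_equal(ep$closure, "extension_after_gap")

  # dx d0, d300, d700; disp d1200; dx d1300: gaps of 400 and 500 close at the
  # last event; the inter-episode dispensation never starts an episode
  ev <- ev_stream(c(0, 300, 700, 1200, 1300),
                  c("diagnosis", "diagnosis", "diagnosis", "dispensation", "diagnosis"),
                  c(NA, NA, NA, 30L, NA))
  ep <- build_episodes(ev, data_end = far_end)
  expect_equal(as.numeric(ep$start_date - D("2012-01-01")), c(0, 700, 1300))
  expect_equal(as.numeric(ep$end_date - D("2012-01-01")), c(300, 700, 1300))
  expect_equal(ep$closure, c("gap", "gap", "gap"))

  # same stream at the 180-day sensitivity setting: strictly more, shorter episodes
  ep180 <- build_episodes(ev, episode_params(gap_days = 180), data_end = far_end)
  expect_gt(nrow(ep180), nrow(ep))
  expect_lte(as.numeric(ep180$end_date[1] - ep180$start_date[1]),
             as.numeric(ep$end_date[1] - ep$start_date[1]))
})

test_that("supply extension is capped and same-day events collapse", {
  ep <- build_episodes(ev_stream(c(0, 100), c("diagnosis", "dispensation"),
                                 c(NA, 250L)), data_end = far_end)
  expect_equal(as.numeric(ep$end_date - D("2012-01-01")), 200)  # min(250, 100)

  # same-day diagnosis + dispensation keeps both roles: the day can close with
  # an extension, and a later same-day pattern can restart an episode
  ev <- ev_stream(c(0, 50, 50, 600), c("diagnosis", "diagnosis", "dispensation",
                                       "diagnosis"), c(NA, NA, 40L, NA))
  ep <- build_episodes(ev, data_end = far_end)
  expect_equal(as.numeric(ep$end_date - D("2012-01-01")), c(90, 600))
  expect_equal(ep$closure[1], "extension_after_gap")
  expect_equal(ep$n_events, c(2L, 1L))
})

test_that("an episode too close to the data end is left open", {
  ep <- build_episodes(ev_stream(c(0, 100), c("diagnosis", "diagnosis")),
                       data_end = D("2012-01-01") + 300)
  expect_equal(ep$closure, "open_at_data_end")
  expect_equal(as.numeric(ep$end_date - D("2012-01-01")), 100)
})

test_that("supply-extended gap checks can bridge a literal gap", {
  ev <- ev_stream(c(0, 100, 500), c("diagnosis", "dispensation", "diagnosis"),
                  c(NA, 100L, NA))
  lit <- build_episodes(ev, data_end = far_end)
  expect_equal(nrow(lit), 2L)  # 400-day raw gap closes the first episode
  ext <- build_episodes(ev, data_end = far_end, supply_extended_gaps = TRUE)
  expect_equal(nrow(ext), 1L)  # supply carries d100 to d200; 300-day gap bridges
  expect_equal(as.numeric(ext$end_date - D("2012-01-01")), 500)
})

test_that("episode boundaries match the brute-force flood-fill oracle", {
  set.seed(99)
  for (rep in 1:200) {
    ev <- rand_stream(sample(2:12, 1))
    G <- sample(c(180L, 365L), 1)
    data_end <- D("2012-01-01") + 3000
    got <- build_episodes(ev, episode_params(gap_days = G), data_end = data_end)
    want <- oracle_episodes(ev, G = G, data_end = data_end)
    expect_equal(got, want, info = paste("stream", rep, "G", G))
  }
})

test_that("gap-rule invariants hold on random streams", {
  set.seed(7)
  for (rep in 1:100) {
    ev <- rand_stream(sample(3:15, 1))
    G <- 365L
    eps <- build_episodes(ev, data_end = D("2012-01-01") + 4000)
    dd <- mddburden:::collapse_days(ev)[order(date)]
    for (k in seq_len(nrow(eps))) {
      inside <- dd[date >= eps$start_date[k] & date <= eps$end_date[k], date]
      if (length(inside) > 1L) expect_lte(max(diff(as.numeric(inside))), G)
    }
    if (nrow(eps) > 1L) {
      # the next episode's first event is more than G after the previous last event
      last_ev <- sapply(seq_len(nrow(eps) - 1L), function(k)
        max(as.numeric(dd[date <= eps$end_date[k], date])))
      expect_true(all(as.numeric(eps$start_date[-1]) - last_ev > G))
    }
    # the extension never exceeds the cap beyond the last event
    ext <- eps[closure == "extension_after_gap"]
    if (nrow(ext)) {
      for (k in seq_len(nrow(ext))) {
        last_ev <- max(dd[date <= ext$end_date[k] & date >= ext$start_date[k] &
                            (has_dx | has_disp), as.numeric(date)])
        expect_lte(as.numeric(ext$end_date[k]) - last_ev, 100)
      }
    }
  }
})

test_that("duration analysis excludes short follow-up and censors open episodes", {
  eps <- rbind(
    data.table(person_id = "A", ordinal = 1L, start_date = D("2013-01-01"),
               end_date = D("2013-01-01") + 398, closure = "gap", n_events = 5L),
    data.table(person_id = "B", ordinal = 1L, start_date = D("2013-01-01"),
               end_date = D("2013-06-01"), closure = "gap", n_events = 2L),
    data.table(person_id = "C", ordinal = 1L, start_date = D("2017-06-01"),
               end_date = D("2018-10-01"), closure = "open_at_data_end", n_events = 9L))
  cen <- data.table(person_id = c("A", "B", "C"),
                    index_date = c(D("2013-01-01"), D("2013-01-01"), D("2017-06-01")),
                    follow_up_end = c(D("2016-01-01"), D("2013-07-20"), D("2018-12-31")))
  dur <- episode_durations(eps, cen)
  expect_setequal(dur$person_id, c("A", "C"))  # B: 200 days of follow-up
  expect_equal(dur[person_id == "A", .(duration_days, observed)],
               data.table(duration_days = 398, observed = TRUE))
  expect_equal(dur[person_id == "C", observed], FALSE)
  expect_equal(dur[person_id == "C", duration_days],
               as.numeric(D("2018-10-01") - D("2017-06-01")))
})

test_that("the product-limit estimator matches closed forms", {
  km <- km_fit(1:5, rep(TRUE, 5))
  expect_equal(km$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)
  # without censoring the KM median is the smallest t with S <= 1/2,
  # i.e. the sample median for odd n
  set.seed(2)
  x <- rexp(201, 0.01)
  km2 <- km_fit(x, rep(TRUE, 201))
  expect_equal(km2$median, median(x))
  # all censored: median not reached
  km3 <- km_fit(c(10, 20), c(FALSE, FALSE))
  expect_true(is.na(km3$median))
})

test_that("the KM median recovers a known log-normal median under light censoring", {
  set.seed(5)
  true <- rlnorm(5000, log(398), 0.6)
  cens <- runif(5000, 400, 4000)
  km <- km_fit(pmin(true, cens), true <= cens)
  expect_lt(abs(km$median - 398) / 398, 0.03)
  expect_true(km$median_ci[1] < km$median && km$median < km$median_ci[2])
})

test_that("shorter gap rule shortens incident episodes monotonically", {
  set.seed(11)
  for (rep in 1:50) {
    ev <- rand_stream(sample(4:14, 1))
    d365 <- build_episodes(ev, episode_params(365), data_end = far_end)
    d180 <- build_episodes(ev, episode_params(180), data_end = far_end)
    expect_lte(as.numeric(d180$end_date[1] - d180$start_date[1]),
               as.numeric(d365$end_date[1] - d365$start_date[1]))
  }
})
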