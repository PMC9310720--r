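# Healthcare-resource-utilization and work-loss burden: monthly mean series
# around the index month and annualized follow-up-weighted means with robust
# (linearized sandwich) standard errors, for cases and matched controls.

#' Monthly healthcare-utilization means
#'
#' Per month -12..+12 around index and per group: mean number of in-person
#' physician outpatient visits (total / primary / psychiatric) and mean
#' inpatient bed days as the overlap of each half-open stay with the calendar
#' month (total / psychiatric / non-psychiatric), over persons at risk.
#'
#' @param cohort `members` table of [build_cohort()].
#' @param tables a `registry_tables` list.
#' @param months month offsets (default -12..12).
#' @return `data.table`: `group`, `m`, `measure` (`visits`/`bed_days`),
#'   `level`, `mean`, `n_at_risk`.
#' @export
monthly_hru <- function(cohort, tables, months = -12L:12L) {
  grid <- burden_grid(cohort, months)

  vis <- tables$visits[physician == TRUE & person_id %chin% grid$person_id]
  vis[, lvl := care3(care_level)]
  vhit <- grid[vis, on = .(person_id, mstart <= date, mend > date), nomatch = NULL,
               .(grow = x.grow, lvl = i.lvl)]
  vis_counts <- function(levels, label) {
    cnt <- vhit[lvl %in% levels, .N, by = grow]
    v <- rep(0, nrow(grid)); v[cnt$grow] <- cnt$N
    agg_series(grid, v, "visits", label)
  }

  st <- tables$stays[person_id %chin% grid$person_id]
  shit <- grid[st, on = .(person_id, mstart < discharge_date, mend > admission_date),
               nomatch = NULL,
               .(grow = x.grow, ward = i.ward,
                 days = overlap_days(i.admission_date, i.discharge_date, x.mstart, x.mend))]
  bed_days <- function(wards, label) {
    dsum <- shit[ward %in% wards, .(d = sum(days)), by = grow]
    v <- rep(0, nrow(grid)); v[dsum$grow] <- dsum$d
    agg_series(grid, v, "bed_days", label)
  }

  out <- data.table::rbindlist(list(
    vis_counts(c("primary", "psychiatric", "other"), "total"),
    vis_counts("primary", "primary"),
    vis_counts("psychiatric", "psychiatric"),
    bed_days(c("psychiatric", "non_psychiatric"), "total"),
    bed_days("psychiatric", "psychiatric"),
    bed_days("non_psychiatric", "non_psychiatric")
  ))
  data.table::setorderv(out, c("measure", "level", "group", "m"))
  out[]
}

#' Monthly work-loss means
#'
#' Restricted to persons aged 20-64 at index. Sick-leave spells shorter than
#' 14 days are dropped (employer-paid); spell days are the overlap with the
#' calendar month scaled by the spell's extent. Reported for total /
#' sick-leave / disability-pension per group and month.
#'
#' @inheritParams monthly_hru
#' @return `data.table`: `group`, `m`, `measure = "workloss_days"`, `level`,
#'   `mean`, `n_at_risk`.
#' @export
monthly_workloss <- function(cohort, tables, months = -12L:12L) {
  wl_cohort <- cohort[age_at_index >= 20L & age_at_index <= 64L]
  grid <- burden_grid(wl_cohort, months)
  wl <- workloss_spells(tables, grid$person_id)
  whit <- grid[wl, on = .(person_id, mstart < end, mend > start), nomatch = NULL,
               .(grow = x.grow, kind = i.kind,
                 days = overlap_days(i.start, i.end, x.mstart, x.mend) * i.extent)]
  series <- function(kinds, label) {
    dsum <- whit[kind %in% kinds, .(d = sum(days)), by = grow]
    v <- rep(0, nrow(grid)); v[dsum$grow] <- dsum$d
    agg_series(grid, v, "workloss_days", label)
  }
  out <- data.table::rbindlist(list(
    series(c("sick_leave", "disability_pension"), "total"),
    series("sick_leave", "sick_leave"),
    series("disability_pension", "disability_pension")
  ))
  data.table::setorderv(out, c("measure", "level", "group", "m"))
  out[]
}

# internal: person x month grid with at-risk flags and a row id
burden_grid <- function(cohort, months) {
  grid <- cohort[, .(person_id, group, index_date, follow_up_end)]
  grid <- grid[rep(seq_len(.N), each = length(months))]
  grid[, m := rep(months, times = .N / length(months))]
  mw <- month_window(grid$index_date, grid$m)
  grid[, `:=`(mstart = mw$start, mend = mw$end)]
  grid <- grid[follow_up_end >= mstart]  # at-risk months only
  grid[, grow := .I]
  grid
}

# internal: sick-leave spells >= 14 days plus disability-pension spells
workloss_spells <- function(tables, person_ids) {
  wl <- tables$workloss[person_id %chin% person_ids]
  wl[kind == "disability_pension" |
       (kind == "sick_leave" & as.numeric(end - start) >= 14)]
}

# internal: per-group/month means of a per-grid-row value
agg_series <- function(grid, v, measure, level) {
  g <- grid[, .(group, m)]
  g[, val := v]
  g[, .(measure = measure, level = level, mean = mean(val), n_at_risk = .N),
    by = .(group, m)]
}

#' Follow-up-weighted annualized mean with robust confidence interval
#'
#' The ratio estimator `mu = sum(x) / sum(w)` where `x` is a person's outcome
#' total in the window and `w` the followed fraction of the window (1 for
#' fully followed persons). The robust (linearized sandwich) standard error is
#' `sqrt(sum((x - mu * w)^2)) / sum(w)`, accounting for the person-level
#' clustering of the monthly data; the 95% CI is normal-theory.
#'
#' @param x numeric outcome totals (counts or days, >= 0).
#' @param w weights in (0, 1].
#' @param outcome,group,window optional labels carried into the result.
#' @return one-row `data.table` of class `burden_estimate`: `outcome`,
#'   `group`, `window`, `estimate`, `se`, `ci_low`, `ci_high`, `n`,
#'   `sum_weights`.
#' @export
weighted_annual_mean <- function(x, w = rep(1, length(x)), outcome = NA_character_,
                                 group = NA_character_, window = NA_character_) {
  stopifnot(length(x) == length(w), length(x) >= 2L, all(w > 0))
  sw <- sum(w)
  if (sw == 0) stop("sum of weights is zero")
  mu <- sum(x) / sw
  se <- sqrt(sum((x - mu * w)^2)) / sw
  out <- data.table::data.table(
    outcome = outcome, group = group, window = window,
    estimate = mu, se = se,
    ci_low = mu - z975 * se, ci_high = mu + z975 * se,
    n = length(x), sum_weights = sw)
  class(out) <- c("burden_estimate", class(out))
  out
}

#' Ratio of two burden estimates, presentation-rounded
#'
#' @param a,b `burden_estimate` rows (or anything with `$estimate`), or bare
#'   numbers.
#' @param digits decimals for half-up rounding (default 1).
#' @return the rounded ratio `a / b`.
#' @export
#' @examples
#' burden_ratio(7.90, 2.48)  # 3.2
burden_ratio <- function(a, b, digits = 1) {
  av <- if (is.numeric(a)) a else a$estimate
  bv <- if (is.numeric(b)) b else b$estimate
  if (bv == 0) stop("reference estimate is zero")
  round_half_up(av / bv, digits)
}

#' Person-level annual outcomes for the burden table
#'
#' Totals per person over the day-based pre-index window `[index - 365,
#' index)` and post-index window `[index, index + 365)` (index day included),
#' with the post-index weight equal to followed days / 365 (the pre window is
#' guaranteed fully observed by the 12-month residency requirement).
#'
#' @param cohort `members` table of [build_cohort()].
#' @param tables a `registry_tables` list.
#' @param days_per_year weight denominator (default 365).
#' @return `data.table`: `person_id`, `group`, `window`, `outcome`, `x`, `w`.
#' @export
annual_outcomes <- function(cohort, tables, days_per_year = 365) {
  win <- data.table::rbindlist(list(
    cohort[, .(person_id, group, age_at_index, window = "pre",
               ws = index_date - 365L, we = index_date, follow_up_end)],
    cohort[, .(person_id, group, age_at_index, window = "post",
               ws = index_date, we = index_date + 365L, follow_up_end)]
  ))
  # followed fraction of the window; follow-up is inclusive of its last day
  win[, w := ifelse(window == "pre", 1,
                    pmin(as.numeric(follow_up_end - ws) + 1, days_per_year) /
                      days_per_year)]
  win[, wrow := .I]

  vis <- tables$visits[physician == TRUE & person_id %chin% cohort$person_id]
  vis[, lvl := care3(care_level)]
  vhit <- win[vis, on = .(person_id, ws <= date, we > date), nomatch = NULL,
              .(wrow = x.wrow, lvl = i.lvl)]
  st <- tables$stays[person_id %chin% cohort$person_id]
  shit <- win[st, on = .(person_id, ws < discharge_date, we > admission_date),
              nomatch = NULL,
              .(wrow = x.wrow, ward = i.ward,
                days = overlap_days(i.admission_date, i.discharge_date, x.ws, x.we))]
  wl <- workloss_spells(tables, cohort$person_id)
  whit <- win[wl, on = .(person_id, ws < end, we > start), nomatch = NULL,
              .(wrow = x.wrow, kind = i.kind, wl_age = x.age_at_index,
                days = overlap_days(i.start, i.end, x.ws, x.we) * i.extent)]
  whit <- whit[wl_age >= 20L & wl_age <= 64L]

  val <- function(hits, sel, value_col, label, restrict_age = FALSE) {
    h <- hits[sel]
    tot <- h[, .(x = sum(get(value_col))), by = wrow]
    base <- if (restrict_age) win[age_at_index >= 20L & age_at_index <= 64L] else win
    out <- data.table::copy(base)[, .(person_id, group, window, w, wrow)]
    out[, x := 0]
    out[tot, on = .(wrow), x := i.x]
    out[, `:=`(outcome = label, wrow = NULL)]
    out
  }
  cnt1 <- function(h) h[, ones := 1][]
  res <- data.table::rbindlist(list(
    val(cnt1(vhit), rep(TRUE, nrow(vhit)), "ones", "visits_total"),
    val(vhit, vhit$lvl == "primary", "ones", "visits_primary"),
    val(vhit, vhit$lvl == "psychiatric", "ones", "visits_psychiatric"),
    val(shit, rep(TRUE, nrow(shit)), "days", "bed_days_total"),
    val(shit, shit$ward == "psychiatric", "days", "bed_days_psychiatric"),
    val(shit, shit$ward == "non_psychiatric", "days", "bed_days_non_psychiatric"),
    val(whit, rep(TRUE, nrow(whit)), "days", "workloss_total", restrict_age = TRUE),
    val(whit, whit$kind == "sick_leave", "days", "workloss_sick_leave", restrict_age = TRUE),
    val(whit, whit$kind == "disability_pension", "days", "workloss_disability_pension",
        restrict_age = TRUE)
  ), use.names = TRUE)
  data.table::setcolorder(res, c("person_id", "group", "window", "outcome", "x", "w"))
  res[]
}

#' Annual burden table (weighted means with robust CIs)
#'
#' One [weighted_annual_mean()] row per outcome x group x window.
#'
#' @inheritParams annual_outcomes
#' @return `data.table` of burden estimates.
#' @export
burden_table <- function(cohort, tables, days_per_year = 365) {
  po <- annual_outcomes(cohort, tables, days_per_year)
  po[, {
    est <- weighted_annual_mean(x, w)
    est[, .(estimate, se, ci_low, ci_high, n, sum_weights)]
  }, by = .(outcome, group, window)][]
}
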