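# Monthly treatment-exposure and comorbidity trajectories on a calendar-month
# grid anchored at the index month (month 0 contains the index date).

#' Coverage window of a dispensation
#'
#' Days supplied are the dispensed tablets divided by tablets-per-day, padded
#' by 25% for variable adherence and rounded up; the window is half-open
#' `[date, date + ceil(days_supplied * 1.25))`.
#'
#' @param date dispensation Date vector.
#' @param tablets dispensed tablet counts.
#' @param tablets_per_day tablets per day (default 1).
#' @param adherence_factor supply multiplier (default 1.25).
#' @return `data.table` with `cover_start`, `cover_end` (half-open).
#' @export
supply_window <- function(date, tablets, tablets_per_day = 1, adherence_factor = 1.25) {
  stopifnot(all(tablets >= 1))
  days <- ceiling(tablets / tablets_per_day * adherence_factor)
  data.table::data.table(cover_start = as.Date(date),
                         cover_end = as.Date(date) + days)
}

# internal: month-m window [start, end) for index dates; m relative to the
# calendar month containing the index date
month_window <- function(index_date, m) {
  s <- add_months(month_start(index_date), m)
  list(start = s, end = add_months(s, 1L))
}

therapy_levels <- c("AD", "addon", "ECT", "rTMS", "psychotherapy")

#' Monthly treatment-exposure grid for the case cohort
#'
#' For every case and month -12..+12 around the index month, flags whether
#' each therapy was ongoing: drug therapies (AD, add-on) count when any
#' dispensation's [supply_window()] intersects the calendar month; procedure
#' therapies (ECT, rTMS, psychotherapy) require at least one procedure record
#' dated inside the month. Months whose window starts after the person's
#' censoring date are not at risk.
#'
#' @param cohort `members` table of [build_cohort()]; the `"mdd"` rows form
#'   the grid.
#' @param tables,codebook as elsewhere.
#' @param tablets_per_day,adherence_factor see [supply_window()].
#' @param months integer vector of month offsets (default -12..12).
#' @return `data.table`: `person_id`, `m`, `therapy`, `treated`, `at_risk`.
#' @export
monthly_exposure <- function(cohort, tables, codebook, tablets_per_day = 1,
                             adherence_factor = 1.25, months = -12L:12L) {
  cases <- cohort[group == "mdd",
                  .(person_id, index_date, follow_up_end)]
  grid <- cases[rep(seq_len(.N), each = length(months))]
  grid[, m := rep(months, times = nrow(cases))]
  mw <- month_window(grid$index_date, grid$m)
  grid[, `:=`(mstart = mw$start, mend = mw$end)]
  grid[, at_risk := follow_up_end >= mstart]

  rx <- tables$dispensations[person_id %chin% cases$person_id]
  is_ad <- match_code(rx$atc, codebook$antidepressant)
  is_addon <- match_code(rx$atc, codebook$addon_med)
  quet <- match_code(rx$atc, codebook$quetiapine_atc)
  is_addon <- is_addon & (!quet | (!is.na(rx$daily_dose_mg) &
                                     rx$daily_dose_mg > codebook$quetiapine_min_daily_dose_mg))
  cover <- function(sel) {
    r <- rx[sel]
    if (nrow(r) == 0L)
      return(data.table::data.table(person_id = character(),
                                    cover_start = as.Date(character()),
                                    cover_end = as.Date(character())))
    sw <- supply_window(r$date, r$tablets, tablets_per_day, adherence_factor)
    data.table::data.table(person_id = r$person_id, sw)
  }
  drug_flag <- function(cov) {
    # grid rows whose half-open month window intersects any coverage window
    hit <- grid[cov, on = .(person_id, mstart < cover_end, mend > cover_start),
                which = TRUE, nomatch = NULL]
    flag <- rep(FALSE, nrow(grid))
    flag[unique(hit)] <- TRUE
    flag
  }
  proc_flag <- function(label) {
    pr <- tables$procedures[procedure == label & person_id %chin% cases$person_id]
    hit <- grid[pr, on = .(person_id, mstart <= date, mend > date),
                which = TRUE, nomatch = NULL]
    flag <- rep(FALSE, nrow(grid))
    flag[unique(hit)] <- TRUE
    flag
  }
  flags <- list(
    AD = drug_flag(cover(is_ad)),
    addon = drug_flag(cover(is_addon)),
    ECT = proc_flag("ECT"),
    rTMS = proc_flag("rTMS"),
    psychotherapy = proc_flag("psychotherapy")
  )
  out <- data.table::rbindlist(lapply(therapy_levels, function(th)
    data.table::data.table(person_id = grid$person_id, m = grid$m, therapy = th,
                           treated = flags[[th]] & grid$at_risk,
                           at_risk = grid$at_risk)))
  data.table::setorderv(out, c("person_id", "m", "therapy"))
  out[]
}

#' Per-month treated proportions from an exposure grid
#'
#' Point mode: share treated among persons at risk that month. Cumulative
#' mode: a person counts from the first at-risk month (from -12 on) in which
#' they were treated and is carried forward even after stopping treatment or
#' being censored; the default denominator is then the full cohort, which
#' makes the curve monotone by construction (`denominator = "at_risk"` gives
#' the censoring-adjusted variant instead). An `"any"` therapy row is the
#' union over the five therapies.
#'
#' @param grid output of [monthly_exposure()].
#' @param mode `"point"` or `"cumulative"`.
#' @param denominator for cumulative mode: `"cohort"` (default) or
#'   `"at_risk"`; point mode always uses at-risk denominators.
#' @return `data.table`: `m`, `therapy` (five therapies plus `"any"`),
#'   `proportion`, `n_treated`, `n_at_risk`.
#' @export
proportion_series <- function(grid, mode = c("point", "cumulative"),
                              denominator = c("cohort", "at_risk")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  g <- data.table::copy(grid)
  any_g <- g[, .(therapy = "any", treated = any(treated), at_risk = at_risk[1L]),
             by = .(person_id, m)]
  g <- data.table::rbindlist(list(g, any_g), use.names = TRUE)
  data.table::setorderv(g, c("therapy", "person_id", "m"))
  if (mode == "point") {
    out <- g[at_risk == TRUE,
             .(proportion = mean(treated), n_treated = sum(treated), n_at_risk = .N),
             by = .(therapy, m)]
  } else {
    g[, ever := cumsum(treated) > 0L, by = .(therapy, person_id)]
    if (denominator == "cohort") {
      out <- g[, .(proportion = mean(ever), n_treated = sum(ever), n_at_risk = .N),
               by = .(therapy, m)]
    } else {
      out <- g[at_risk == TRUE,
               .(proportion = mean(ever), n_treated = sum(ever), n_at_risk = .N),
               by = .(therapy, m)]
    }
  }
  data.table::setorderv(out, c("therapy", "m"))
  out[]
}

#' Cumulative comorbidity series around the index month
#'
#' For each condition in the codebook's comorbidity list, the cumulative
#' proportion of cases carrying the condition per month -12..+12. A person
#' counts from month `max(-12, month of first qualifying diagnosis)` onward;
#' qualifying diagnoses are dated within `lookback_years` before index up to
#' the end of month +12 — older records never qualify. The value in month 0 is
#' the baseline-table convention (conditions recorded within the lookback
#' before or at index).
#'
#' @param cohort `members` of [build_cohort()] (cases used).
#' @param tables,codebook as elsewhere.
#' @param lookback_years lookback before index (default 5).
#' @param conditions condition names (default: the codebook's psychiatric
#'   comorbidities).
#' @param months month offsets (default -12..12).
#' @return `data.table`: `condition`, `m`, `proportion`, `n_with`, `n_at_risk`.
#' @export
comorbidity_series <- function(cohort, tables, codebook, lookback_years = 5,
                               conditions = codebook$psychiatric_comorbidities,
                               months = -12L:12L) {
  cases <- cohort[group == "mdd", .(person_id, index_date, follow_up_end)]
  dx <- tables$diagnoses[person_id %chin% cases$person_id]
  out <- list()
  mmin <- min(months)
  for (cond in conditions) {
    set <- codebook$comorbidities[[cond]]
    if (is.null(set)) stop("unknown comorbidity: ", cond)
    d <- dx[match_code(icd10, set)]
    d <- d[cases, on = .(person_id), nomatch = NULL]
    d <- d[date >= index_date - round(lookback_years * 365.25)]
    d <- d[date < month_window(index_date, max(months))$end]
    if (nrow(d)) {
      first <- d[, .(first_date = min(date), index_date = index_date[1L]), by = person_id]
      first[, m0 := pmax(mmin, month_diff(first_date, index_date))]
    } else {
      first <- data.table::data.table(person_id = character(), m0 = integer())
    }
    per <- cases[rep(seq_len(.N), each = length(months))]
    per[, m := rep(months, times = nrow(cases))]
    per[, at_risk := follow_up_end >= month_window(index_date, m)$start]
    per[, m0 := first[per, on = .(person_id), x.m0]]
    per[, has := !is.na(m0) & m >= m0]
    out[[cond]] <- per[at_risk == TRUE,
                       .(condition = cond, proportion = mean(has),
                         n_with = sum(has), n_at_risk = .N), by = m]
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("condition", "m"))
  data.table::setorderv(res, c("condition", "m"))
  res[]
}
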