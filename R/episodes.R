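# MDD treatment-episode construction: stitch depressive events into episodes
# with a maximum-gap rule, extend supply-closed episodes by the dispensed
# tablet count (capped), and estimate episode duration by Kaplan-Meier.

#' Episode-algorithm parameters
#'
#' @param gap_days maximum interval between consecutive depressive events for
#'   an episode to stay ongoing (default 365; sensitivity analysis 180).
#' @param extension_cap_days cap on the supply-based extension when the last
#'   event of an episode is a dispensation (default 100).
#' @param tablets_per_day tablets consumed per day when converting a dispensed
#'   tablet count to days of supply (default 1).
#' @return list of class `episode_params`.
#' @export
episode_params <- function(gap_days = 365L, extension_cap_days = 100L,
                           tablets_per_day = 1) {
  stopifnot(gap_days > 0, extension_cap_days > 0, tablets_per_day > 0)
  structure(list(gap_days = as.integer(gap_days),
                 extension_cap_days = as.integer(extension_cap_days),
                 tablets_per_day = tablets_per_day),
            class = "episode_params")
}

# internal: collapse same-day events; a day keeps a diagnosis flag (can start
# a new episode) and a dispensation flag with the summed tablet count (drives
# the supply extension when the day closes an episode)
collapse_days <- function(events) {
  ev <- data.table::as.data.table(events)
  ev[, .(has_dx = any(event_class == "diagnosis"),
         has_disp = any(event_class == "dispensation"),
         tablets = sum(tablets[event_class == "dispensation"], na.rm = TRUE)),
     by = date]
}

#' Stitch one person's depressive events into MDD episodes
#'
#' Scanning from the first-ever MDD diagnosis: an inter-event gap of at most
#' `gap_days` keeps the episode ongoing; a larger gap closes it at the last
#' event's date. When the closing event is an antidepressant or add-on
#' dispensation, the episode end is extended by the number of dispensed
#' tablets converted to days of supply, capped at `extension_cap_days`. After
#' closure only a subsequent MDD *diagnosis* starts the next episode;
#' dispensations and procedures between episodes are ignored. The last episode
#' is left open (uncloseable) when the data end is within `gap_days` of its
#' last event. Gap checks use raw event dates; optionally
#' (`supply_extended_gaps = TRUE`) a dispensation's date is carried forward by
#' its capped days of supply before the gap check.
#'
#' @param events depressive events of one person as from [depressive_events()]
#'   (columns `date`, `event_class`, `tablets`), sorted; the first event must
#'   be the first-ever MDD diagnosis.
#' @param params an [episode_params()] list.
#' @param data_end last date observable for this person (administrative end of
#'   data, or the person's censoring date).
#' @param supply_extended_gaps use supply-carried dates in the gap checks
#'   (default `FALSE`: literal event dates).
#' @return `data.table`: `ordinal`, `start_date`, `end_date`, `closure` in
#'   `{"gap", "extension_after_gap", "open_at_data_end"}`, `n_events`
#'   (collapsed event days).
#' @export
build_episodes <- function(events, params = episode_params(), data_end,
                           supply_extended_gaps = FALSE) {
  if (is.null(events) || nrow(events) == 0L) stop("no events: person has no index diagnosis")
  data_end <- as.Date(data_end)
  dd <- collapse_days(events)
  data.table::setorderv(dd, "date")
  if (!dd$has_dx[1L]) stop("first event must be an MDD diagnosis")
  dd <- dd[date <= data_end]

  G <- params$gap_days
  cap <- params$extension_cap_days
  supply_days <- function(tab) min(floor(tab / params$tablets_per_day), cap)

  n <- nrow(dd)
  d <- as.numeric(dd$date)
  # effective date used in gap checks (optionally supply-carried)
  eff <- d
  if (supply_extended_gaps)
    eff <- d + ifelse(dd$has_disp, pmin(floor(dd$tablets / params$tablets_per_day), cap), 0)

  eps <- list()
  i <- 1L
  repeat {
    start <- i
    last <- i
    j <- i + 1L
    while (j <= n && (d[j] - eff[last]) <= G) {
      last <- j
      j <- j + 1L
    }
    # episode spans collapsed days start..last
    open <- (as.numeric(data_end) - eff[last]) <= G
    if (open) {
      end <- d[last]
      closure <- "open_at_data_end"
    } else if (dd$has_disp[last]) {
      end <- d[last] + supply_days(dd$tablets[last])
      closure <- "extension_after_gap"
    } else {
      end <- d[last]
      closure <- "gap"
    }
    eps[[length(eps) + 1L]] <- data.table::data.table(
      start_date = dd$date[start],
      end_date = as.Date(end, origin = "1970-01-01"),
      closure = closure, n_events = last - start + 1L)
    # next episode starts at the next diagnosis day after `last`
    j <- last + 1L
    while (j <= n && !dd$has_dx[j]) j <- j + 1L
    if (j > n) break
    i <- j
  }
  out <- data.table::rbindlist(eps)
  out[, ordinal := seq_len(.N)]
  data.table::setcolorder(out, c("ordinal", "start_date", "end_date", "closure", "n_events"))
  out[]
}

#' Build incident episodes for a whole cohort
#'
#' Runs [build_episodes()] per case on events truncated at each person's
#' censoring date.
#'
#' @param cohort the `members` table of [build_cohort()] (cases only are used).
#' @param tables,codebook as elsewhere.
#' @param params an [episode_params()] list.
#' @return `data.table` with `person_id` and the per-episode columns.
#' @export
cohort_episodes <- function(cohort, tables, codebook, params = episode_params()) {
  cases <- cohort[group == "mdd"]
  ev <- depressive_events(tables, codebook, person_id = cases$person_id)
  ev <- ev[cases[, .(person_id, index_date, follow_up_end)], on = .(person_id)]
  ev <- ev[date >= index_date & date <= follow_up_end]
  ev[, .(eps = list(build_episodes(.SD, params, data_end = follow_up_end[1L]))),
     by = person_id][, eps[[1L]], by = person_id]
}

#' Incident-episode durations for survival analysis
#'
#' Restricts to persons with at least `min_follow_up_days` of follow-up, and
#' returns the duration of the incident (ordinal-1) episode with an observed
#' flag: censored when the episode is still open at the data end or the
#' censoring date precedes its closure.
#'
#' @param episodes per-person episode table (from [cohort_episodes()], or any
#'   table with `person_id`, `ordinal`, `start_date`, `end_date`, `closure`).
#' @param censor_info table with `person_id`, `index_date`, `follow_up_end`.
#' @param min_follow_up_days minimum follow-up (default 365).
#' @return `data.table`: `person_id`, `duration_days`, `observed`.
#' @export
episode_durations <- function(episodes, censor_info, min_follow_up_days = 365L) {
  ep1 <- episodes[ordinal == 1L]
  ep1 <- ep1[censor_info, on = .(person_id), nomatch = NULL]
  ep1 <- ep1[as.numeric(follow_up_end - index_date) >= min_follow_up_days]
  ep1[, observed := closure %in% c("gap", "extension_after_gap") &
        end_date <= follow_up_end]
  ep1[, duration_days := as.numeric(pmin(end_date, follow_up_end) - start_date)]
  ep1[, .(person_id, duration_days, observed)]
}

#' Kaplan-Meier fit of episode duration
#'
#' Product-limit estimator with Greenwood variance and log-log pointwise
#' confidence bands; the median is the smallest time with survival at or below
#' one half, with its confidence interval read off the banded curve
#' (Brookmeyer-Crowley).
#'
#' @param durations numeric durations (days).
#' @param observed logical; `FALSE` marks right-censored durations.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `km_fit`: `time`, `surv`, `n_risk`, `ci_low`,
#'   `ci_high`, `median`, `median_ci` (NA when the median is not reached),
#'   `n`, `n_events`.
#' @export
km_fit <- function(durations, observed, conf_level = 0.95) {
  stopifnot(length(durations) >= 1L, length(durations) == length(observed))
  sf <- survival::survfit(survival::Surv(durations, observed) ~ 1,
                          conf.type = "log-log", conf.int = conf_level)
  qs <- stats::quantile(sf, probs = 0.5)
  med <- unname(qs$quantile)
  out <- list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
              ci_low = sf$lower, ci_high = sf$upper,
              median = med,
              median_ci = c(unname(qs$lower), unname(qs$upper)),
              n = sf$n, n_events = sum(sf$n.event))
  class(out) <- "km_fit"
  out
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: n = %d, events = %d\n", x$n, x$n_events))
  if (is.na(x$median)) cat("median: not reached\n")
  else cat(sprintf("median %.0f days (95%% CI: %.0f-%.0f)\n",
                   x$median, x$median_ci[1], x$median_ci[2]))
  invisible(x)
}
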