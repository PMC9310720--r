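# Care-level pathway: classify each case at 0/3/6/9/12 months after index by
# the care level of the most recent depressive event, and count transitions
# between consecutive timepoints (the alluvial-flow table).

referral_timepoints <- c(`0` = 0L, `3` = 91L, `6` = 182L, `9` = 273L, `12` = 365L)

#' Care-level states of cases at the 3-month timepoints
#'
#' The state at a timepoint is the care level (primary / psychiatric / other)
#' of the latest depressive event carrying a care level dated on or before
#' the timepoint date (the index diagnosis included); dispensations carry no
#' care level and never change the state. Timepoints after the censoring date
#' are `"censored"`, and stay censored thereafter.
#'
#' @param cohort `members` table of [build_cohort()] (cases used).
#' @param tables,codebook as elsewhere.
#' @param timepoint_days named integer vector of day offsets
#'   (default 0/91/182/273/365 for months 0/3/6/9/12).
#' @return `data.table`: `person_id`, `timepoint` (months), `state`.
#' @export
referral_states <- function(cohort, tables, codebook,
                            timepoint_days = referral_timepoints) {
  cases <- cohort[group == "mdd", .(person_id, index_date, follow_up_end)]
  ev <- depressive_events(tables, codebook, person_id = cases$person_id)
  ev <- ev[!is.na(care_level)]
  ev <- ev[cases, on = .(person_id), nomatch = NULL]
  ev <- ev[date >= index_date & date <= follow_up_end]
  ev[, lvl := care3(care_level)]
  # same-day tie-break mirrors the index rule: psychiatric > primary > other
  ev[, rank := match(lvl, c("psychiatric", "primary", "other"))]
  data.table::setorderv(ev, c("person_id", "date", "rank"))
  # per day keep the highest-priority level
  ev <- ev[, .(lvl = lvl[1L]), by = .(person_id, date)]

  out <- list()
  for (tp in names(timepoint_days)) {
    td <- cases$index_date + timepoint_days[[tp]]
    q <- data.table::data.table(person_id = cases$person_id, tdate = td)
    last <- ev[q, on = .(person_id, date <= tdate), mult = "last",
               .(person_id, state = x.lvl)]
    st <- data.table::data.table(person_id = cases$person_id,
                                 timepoint = as.integer(tp),
                                 state = last$state)
    st[cases$follow_up_end < td, state := "censored"]
    out[[tp]] <- st
  }
  res <- data.table::rbindlist(out)
  data.table::setorderv(res, c("person_id", "timepoint"))
  res[]
}

#' Transition counts between consecutive timepoints, plus the referral share
#'
#' @param states output of [referral_states()].
#' @param cohort `members` table (used for the index care level of cases).
#' @param tables,codebook needed for the event-based referral share.
#' @param share_method `"events"` (default): the share of primary-index cases
#'   with any psychiatric-level depressive event within days 1..365, among
#'   those still followed at month 12; `"states"`: ever in state psychiatric
#'   at months 3-12.
#' @return list: `flows` (`t_from`, `t_to`, `state_from`, `state_to`, `n`)
#'   and `share_primary_to_psychiatric`.
#' @export
flow_table <- function(states, cohort, tables, codebook,
                       share_method = c("events", "states")) {
  share_method <- match.arg(share_method)
  tps <- sort(unique(states$timepoint))
  flows <- list()
  for (i in seq_len(length(tps) - 1L)) {
    a <- states[timepoint == tps[i], .(person_id, state_from = state)]
    b <- states[timepoint == tps[i + 1L], .(person_id, state_to = state)]
    ab <- merge(a, b, by = "person_id")
    fl <- ab[, .N, by = .(state_from, state_to)]
    fl[, `:=`(t_from = tps[i], t_to = tps[i + 1L])]
    flows[[i]] <- fl
  }
  flows <- data.table::rbindlist(flows)
  data.table::setcolorder(flows, c("t_from", "t_to", "state_from", "state_to", "N"))
  data.table::setnames(flows, "N", "n")
  data.table::setorderv(flows, c("t_from", "state_from", "state_to"))

  cases <- cohort[group == "mdd"]
  primary_idx <- cases[care_level_at_index == "primary",
                       .(person_id, index_date, follow_up_end)]
  followed <- primary_idx[as.numeric(follow_up_end - index_date) >= 365]
  if (share_method == "events") {
    ev <- depressive_events(tables, codebook, person_id = followed$person_id)
    ev <- ev[!is.na(care_level) & care3(care_level) == "psychiatric"]
    ev <- ev[followed, on = .(person_id), nomatch = NULL]
    ev <- ev[date > index_date & date <= index_date + 365L]
    n_psy <- data.table::uniqueN(ev$person_id)
  } else {
    st <- states[person_id %chin% followed$person_id & timepoint > 0L]
    n_psy <- data.table::uniqueN(st[state == "psychiatric", person_id])
  }
  share <- if (nrow(followed)) n_psy / nrow(followed) else NA_real_
  list(flows = flows[], share_primary_to_psychiatric = share)
}
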