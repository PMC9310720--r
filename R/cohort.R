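# Cohort construction: incident-case identification, unipolarity and washout
# exclusions, eligibility-screened matched controls (with replacement), and
# per-person censoring.

care3 <- function(care_level) {
  data.table::fcase(care_level %in% c("psychiatric_outpatient", "psychiatric_inpatient"),
                    "psychiatric",
                    care_level == "primary", "primary",
                    default = "other")
}

#' Whole years between two dates
#' @param birth_date,at Date vectors.
#' @return integer ages, `floor((at - birth) / 365.25)`.
#' @export
age_at <- function(birth_date, at) {
  as.integer(floor(as.numeric(at - birth_date) / 365.25))
}

#' Find incident MDD cases
#'
#' A person is an incident case when their first-ever MDD diagnosis falls
#' inside the inclusion window. The care level at index is taken from the
#' index-day diagnoses, collapsed to primary/psychiatric/other; when the same
#' day carries several care levels the psychiatric level wins, then primary,
#' then other (specialist recording treated as authoritative).
#'
#' @param tables a `registry_tables` list.
#' @param codebook an `mdd_codebook`.
#' @param inclusion_window length-2 Date (or string) vector, half-open
#'   `[start, end)`.
#' @return `data.table` of index events: `person_id`, `index_date`,
#'   `care_level_at_index`, `age_at_index`, `sex`, `municipality`.
#' @export
find_incident_cases <- function(tables, codebook,
                                inclusion_window = c("2012-01-01", "2019-01-01")) {
  iw <- as.Date(inclusion_window)
  mdd <- tables$diagnoses[match_code(icd10, codebook$mdd)]
  if (nrow(mdd) == 0L) return(empty_index_events())
  first <- mdd[, .(index_date = min(date)), by = person_id]
  first <- first[index_date >= iw[1] & index_date < iw[2]]
  if (nrow(first) == 0L) return(empty_index_events())
  # care level at index: all MDD diagnoses on the index day, best level wins
  day0 <- mdd[first, on = .(person_id, date = index_date), nomatch = NULL]
  day0[, lvl := care3(care_level)]
  day0[, rank := match(lvl, c("psychiatric", "primary", "other"))]
  lvl <- day0[, .(care_level_at_index = lvl[which.min(rank)]), by = person_id]
  out <- merge(first, lvl, by = "person_id")
  out <- merge(out, tables$persons[, .(person_id, sex, birth_date, municipality)],
               by = "person_id")
  out[, age_at_index := age_at(birth_date, index_date)]
  out[, birth_date := NULL]
  data.table::setkeyv(out, "person_id")
  out[]
}

empty_index_events <- function() {
  data.table::data.table(person_id = character(), index_date = as.Date(character()),
                         care_level_at_index = character(), age_at_index = integer(),
                         sex = character(), municipality = character())
}

# internal: per-person date of first exclusion diagnosis (psychosis, bipolar,
# mania, dementia), or NA
first_exclusion_dx <- function(tables, codebook) {
  sets <- list(codebook$psychosis, codebook$bipolar, codebook$mania, codebook$dementia)
  hit <- Reduce(`|`, lapply(sets, function(s) match_code(tables$diagnoses$icd10, s)))
  ex <- tables$diagnoses[hit %in% TRUE]
  if (nrow(ex) == 0L)
    return(data.table::data.table(person_id = character(),
                                  first_excl = as.Date(character())))
  ex[, .(first_excl = min(date)), by = person_id]
}

# internal: TRUE when one residency interval covers [from, to] entirely
covers_interval <- function(residency, person_id, from, to) {
  q <- data.table::data.table(person_id = person_id, from = from, to = to)
  idx <- residency[q, on = .(person_id, start <= from, end > to), which = TRUE]
  !is.na(idx)
}

#' Apply the unipolarity and washout exclusions to incident cases
#'
#' Removes cases with any psychosis/bipolar/mania/dementia diagnosis dated on
#' or before the index date, and cases without continuous residency covering
#' the 365 days before index (the washout needed to observe history).
#'
#' @param cases output of [find_incident_cases()].
#' @param tables,codebook as elsewhere.
#' @return the filtered `cases` table.
#' @export
apply_exclusions <- function(cases, tables, codebook) {
  if (nrow(cases) == 0L) return(cases)
  ex <- first_exclusion_dx(tables, codebook)
  cases <- merge(cases, ex, by = "person_id", all.x = TRUE)
  cases <- cases[is.na(first_excl) | first_excl > index_date]
  cases[, first_excl := NULL]
  keep <- covers_interval(tables$residency, cases$person_id,
                          cases$index_date - 365L, cases$index_date)
  cases[keep]
}

# internal: person-level eligibility facts for control screening
control_facts <- function(tables, codebook) {
  p <- tables$persons[, .(person_id, sex, birth_date, municipality, death_date)]
  dep <- tables$diagnoses[match_code(icd10, codebook$mdd), unique(person_id)]
  sh <- tables$diagnoses[match_code(icd10, codebook$self_harm), unique(person_id)]
  ad <- tables$dispensations[match_code(atc, codebook$antidepressant), unique(person_id)]
  p[, never_dep := !person_id %chin% c(dep, sh, ad)]
  ex <- first_exclusion_dx(tables, codebook)
  p <- merge(p, ex, by = "person_id", all.x = TRUE)
  p
}

#' Is a person an eligible control at a given index date?
#'
#' Eligibility demands: no depression diagnosis, intentional self-harm code or
#' antidepressant dispensation anywhere in the data window; no
#' psychosis/bipolar/mania/dementia history on or before the index date;
#' continuous residency over the 365 days up to the index date; and being
#' alive and resident on the index date.
#'
#' @param person_id character vector of candidate ids.
#' @param index_date Date vector (recycled) of index dates to inherit.
#' @param tables,codebook as elsewhere.
#' @return logical vector.
#' @export
eligible_control <- function(person_id, index_date, tables, codebook) {
  facts <- control_facts(tables, codebook)
  q <- data.table::data.table(person_id = as.character(person_id),
                              index_date = as.Date(index_date))
  q <- facts[q, on = .(person_id)]  # right join: preserves query order
  ok <- !is.na(q$sex) & q$never_dep %in% TRUE &
    (is.na(q$first_excl) | q$first_excl > q$index_date) &
    (is.na(q$death_date) | q$death_date > q$index_date)
  ok & covers_interval(tables$residency, q$person_id,
                       q$index_date - 365L, q$index_date)
}

#' Match controls to cases, with replacement
#'
#' For each case, one control is sampled uniformly at random (seeded) from the
#' stratum of eligible persons of the same sex and municipality whose age at
#' the case's index date differs by at most 2 whole years. Controls inherit
#' the case's index date; sampling is with replacement across cases; cases
#' with an empty stratum are kept with `control_id = NA`.
#'
#' @param cases output of [apply_exclusions()].
#' @param tables,codebook as elsewhere.
#' @param seed integer seed for the sampling stream.
#' @return `data.table`: `case_id`, `control_id` (`NA` when unmatched),
#'   `index_date`.
#' @export
match_controls <- function(cases, tables, codebook, seed = 1L) {
  if (nrow(cases) == 0L)
    return(data.table::data.table(case_id = character(), control_id = character(),
                                  index_date = as.Date(character())))
  facts <- control_facts(tables, codebook)
  pool <- facts[never_dep == TRUE & !person_id %chin% cases$person_id]
  res <- tables$residency

  cs <- cases[, .(case_id = person_id, index_date, sex, municipality,
                  age = age_at_index)]
  # candidate join on sex + municipality, then the age caliper and date rules
  cand <- merge(cs, pool, by = c("sex", "municipality"),
                allow.cartesian = TRUE, suffixes = c("", ".ctl"))
  cand[, age_ctl := age_at(birth_date, index_date)]
  cand <- cand[abs(age - age_ctl) <= 2L]
  cand <- cand[is.na(first_excl) | first_excl > index_date]
  cand <- cand[is.na(death_date) | death_date > index_date]
  cand <- cand[covers_interval(res, person_id, index_date - 365L, index_date)]

  # seeded uniform pick of one candidate per case: smallest hash wins, so the
  # draw is independent of candidate order
  cand[, u := hash_unif(seed, as.numeric(factor(case_id)) * 1e6 +
                          as.numeric(factor(person_id)), 7L)]
  pickd <- cand[, .SD[which.min(u)], by = case_id][, .(case_id, control_id = person_id)]
  out <- merge(cs[, .(case_id, index_date)], pickd, by = "case_id", all.x = TRUE)
  data.table::setcolorder(out, c("case_id", "control_id", "index_date"))
  data.table::setkeyv(out, "case_id")
  out[]
}

#' Censoring date and reason for a cohort member
#'
#' Follow-up ends at the earliest of death, emigration (end of the residency
#' interval containing the index date), the first post-index exclusion
#' diagnosis (psychosis/bipolar/mania/dementia), or the administrative end of
#' data. Date ties resolve death > emigration > exclusion; end of data only
#' applies when nothing else intervenes by then.
#'
#' @param person_id character vector.
#' @param index_date Date vector (one per person).
#' @param tables,codebook as elsewhere.
#' @param end_of_data last day with data (default `"2018-12-31"`).
#' @return `data.table`: `person_id`, `index_date`, `follow_up_end`, `reason`
#'   in `{"death", "emigration", "exclusion_dx", "end_of_data"}`.
#' @export
censor <- function(person_id, index_date, tables, codebook,
                   end_of_data = as.Date("2018-12-31")) {
  end_of_data <- as.Date(end_of_data)
  q <- data.table::data.table(person_id = as.character(person_id),
                              index_date = as.Date(index_date))
  q[, death_date := tables$persons[q, on = .(person_id), x.death_date]]
  # residency interval containing the index date; its end (minus one day,
  # half-open) is the emigration date when before end_of_data
  res <- tables$residency
  ridx <- res[q, on = .(person_id, start <= index_date, end > index_date),
              mult = "first", which = TRUE]
  emig <- rep(as.Date(NA), nrow(q))
  has <- !is.na(ridx)
  emig[has] <- res$end[ridx[has]] - 1L
  emig[!is.na(emig) & emig >= end_of_data] <- NA

  sets <- list(codebook$psychosis, codebook$bipolar, codebook$mania, codebook$dementia)
  hit <- Reduce(`|`, lapply(sets, function(s) match_code(tables$diagnoses$icd10, s)))
  ex <- suppressWarnings(
    tables$diagnoses[hit][q, on = .(person_id, date > index_date),
                          .(first_excl = min(x.date)), by = .EACHI])
  fe <- as.numeric(ex$first_excl)
  fe[!is.finite(fe)] <- NA_real_
  q[, excl_date := as.Date(fe, origin = "1970-01-01")]

  cand <- data.table::data.table(
    death = as.numeric(q$death_date),
    emigration = as.numeric(emig),
    exclusion_dx = as.numeric(q$excl_date),
    end_of_data = as.numeric(end_of_data)
  )
  m <- as.matrix(cand)
  m[is.na(m)] <- Inf
  best <- max.col(-m, ties.method = "first")  # ties: earlier column wins
  fu <- m[cbind(seq_len(nrow(m)), best)]
  out <- data.table::data.table(
    person_id = q$person_id, index_date = q$index_date,
    follow_up_end = as.Date(fu, origin = "1970-01-01"),
    reason = colnames(m)[best]
  )
  out[, follow_up_end := pmax(follow_up_end, index_date)]
  out[]
}

#' Build the full matched cohort with censoring
#'
#' Convenience wrapper running [find_incident_cases()], [apply_exclusions()],
#' [match_controls()] and [censor()] for cases and their controls.
#'
#' @param tables,codebook as elsewhere.
#' @param inclusion_window half-open Date window for incident diagnoses.
#' @param seed matching seed.
#' @param end_of_data administrative censoring date.
#' @return list with `cases` (index events), `pairs` (matched pairs), and
#'   `members`: one row per followed individual (`person_id`, `group`,
#'   `pair_id`, `index_date`, `care_level_at_index`, `age_at_index`, `sex`,
#'   `follow_up_end`, `reason`).
#' @export
build_cohort <- function(tables, codebook,
                         inclusion_window = c("2012-01-01", "2019-01-01"),
                         seed = 1L, end_of_data = as.Date("2018-12-31")) {
  cases <- find_incident_cases(tables, codebook, inclusion_window)
  cases <- apply_exclusions(cases, tables, codebook)
  pairs <- match_controls(cases, tables, codebook, seed = seed)

  ca <- cases[, .(person_id, group = "mdd", pair_id = person_id, index_date,
                  care_level_at_index, age_at_index, sex)]
  matched <- pairs[!is.na(control_id)]
  co <- merge(matched[, .(person_id = control_id, pair_id = case_id, index_date)],
              tables$persons[, .(person_id, sex, birth_date)], by = "person_id")
  co <- co[, .(person_id, group = "control", pair_id, index_date,
               care_level_at_index = NA_character_,
               age_at_index = age_at(birth_date, index_date), sex)]
  members <- data.table::rbindlist(list(ca, co), use.names = TRUE)
  cen <- censor(members$person_id, members$index_date, tables, codebook, end_of_data)
  members[, `:=`(follow_up_end = cen$follow_up_end, reason = cen$reason)]
  data.table::setorderv(members, c("pair_id", "group"))
  list(cases = cases, pairs = pairs, members = members)
}
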