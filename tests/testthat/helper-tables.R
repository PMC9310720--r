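# Builders for small in-code registry fixtures.

library(data.table)

D <- function(x) as.Date(x)

# assemble registry tables from partial row sets; missing tables stay empty
mk_tables <- function(...) {
  tabs <- mddburden:::empty_tables()
  mods <- list(...)
  for (nm in names(mods)) {
    add <- as.data.table(mods[[nm]])
    tabs[[nm]] <- rbind(tabs[[nm]], add, fill = TRUE)
  }
  class(tabs) <- c("registry_tables", "list")
  tabs
}

person_row <- function(id, sex = "F", birth = "1980-01-01", muni = "M01",
                       death = NA) {
  data.table(person_id = id, sex = sex, birth_date = D(birth),
             municipality = muni, death_date = D(death))
}

residency_row <- function(id, start = "2010-01-01", end = "2019-01-01") {
  data.table(person_id = id, start = D(start), end = D(end))
}

dx_row <- function(id, date, icd10 = "F329", care = "primary") {
  data.table(person_id = id, date = D(date), icd10 = icd10, care_level = care)
}

rx_row <- function(id, date, atc = "N06AB10", tablets = 100L, dose = NA_real_) {
  data.table(person_id = id, date = D(date), atc = atc,
             tablets = as.integer(tablets), daily_dose_mg = dose)
}

proc_row <- function(id, date, procedure = "psychotherapy", care = "primary") {
  data.table(person_id = id, date = D(date), procedure = procedure,
             care_level = care)
}

# a minimal cohort `members` row, bypassing build_cohort for unit tests
member_row <- function(id, index, fu_end, group = "mdd", care = "primary",
                       age = 40L, sex = "F", reason = "end_of_data") {
  data.table(person_id = id, group = group, pair_id = id,
             index_date = D(index), care_level_at_index = care,
             age_at_index = as.integer(age), sex = sex,
             follow_up_end = D(fu_end), reason = reason)
}

# depressive-event rows for build_episodes (dates as day offsets from a base)
ev_stream <- function(days, classes, tablets = NA_integer_,
                      base = D("2012-01-01")) {
  data.table(person_id = "P1", date = base + days, event_class = classes,
             care_level = ifelse(classes == "dispensation", NA_character_, "primary"),
             tablets = as.integer(tablets), code = "x")
}
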