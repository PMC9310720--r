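#' Registry table schemas
#'
#' Declares the seven CSV schemas of the registry extract: column names, types
#' and the table-level invariants enforced by [load_tables()].
#'
#' @return named list; one element per table with `cols` (name -> type, where
#'   type is one of `"character"`, `"date"`, `"integer"`, `"numeric"`,
#'   `"logical"`) and `levels` for categorical columns.
#' @export
registry_schemas <- function() {
  list(
    persons = list(cols = c(person_id = "character", sex = "character",
                            birth_date = "date", municipality = "character",
                            death_date = "date"),
                   levels = list(sex = c("F", "M"))),
    residency = list(cols = c(person_id = "character", start = "date", end = "date"),
                     levels = list()),
    diagnoses = list(cols = c(person_id = "character", date = "date",
                              icd10 = "character", care_level = "character"),
                     levels = list(care_level = c("primary", "psychiatric_outpatient",
                                                  "psychiatric_inpatient", "other"))),
    dispensations = list(cols = c(person_id = "character", date = "date",
                                  atc = "character", tablets = "integer",
                                  daily_dose_mg = "numeric"),
                         levels = list()),
    procedures = list(cols = c(person_id = "character", date = "date",
                               procedure = "character", care_level = "character"),
                      levels = list(procedure = c("ECT", "rTMS", "psychotherapy"),
                                    care_level = c("primary", "psychiatric_outpatient",
                                                   "psychiatric_inpatient", "other"))),
    visits = list(cols = c(person_id = "character", date = "date",
                           care_level = "character", physician = "logical"),
                  levels = list(care_level = c("primary", "psychiatric_outpatient",
                                               "psychiatric_inpatient", "other"))),
    stays = list(cols = c(person_id = "character", admission_date = "date",
                          discharge_date = "date", ward = "character"),
                 levels = list(ward = c("psychiatric", "non_psychiatric"))),
    workloss = list(cols = c(person_id = "character", start = "date",
                             end = "date", kind = "character",
                             extent = "numeric"),
                    levels = list(kind = c("sick_leave", "disability_pension")))
  )
}

icd10_pattern <- "^[A-Z][0-9]{2}[0-9A-Z]{0,2}$"
atc_pattern <- "^[A-Z][0-9]{2}[A-Z]{0,2}([0-9]{2})?$"

# internal: row-level invariant check for one table; returns logical keep-vector
# with attribute "why" describing the first failure mode found
table_invariants <- function(name, dt) {
  ok <- rep(TRUE, nrow(dt))
  why <- character()
  bad <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) why <<- c(why, msg)
    ok & !(cond %in% TRUE)
  }
  switch(name,
    persons = {
      ok <- bad(!dt$sex %in% c("F", "M"), "sex must be F or M")
      ok <- bad(is.na(dt$birth_date), "unparseable birth_date")
      ok <- bad(!is.na(dt$death_date) & dt$death_date < dt$birth_date,
                "death_date before birth_date")
    },
    residency = {
      ok <- bad(is.na(dt$start) | is.na(dt$end), "unparseable date")
      ok <- bad(dt$end <= dt$start, "empty or inverted residency interval")
    },
    diagnoses = {
      ok <- bad(is.na(dt$date), "unparseable date")
      ok <- bad(!grepl(icd10_pattern, dt$icd10),
                paste0("icd10 must match ", icd10_pattern))
      ok <- bad(!dt$care_level %in% registry_schemas()$diagnoses$levels$care_level,
                "unknown care_level")
    },
    dispensations = {
      ok <- bad(is.na(dt$date), "unparseable date")
      ok <- bad(!grepl(atc_pattern, dt$atc), paste0("atc must match ", atc_pattern))
      ok <- bad(is.na(dt$tablets) | dt$tablets < 1L, "tablets must be >= 1")
      ok <- bad(!is.na(dt$daily_dose_mg) & dt$daily_dose_mg <= 0,
                "daily_dose_mg must be positive")
    },
    procedures = {
      ok <- bad(is.na(dt$date), "unparseable date")
      ok <- bad(!dt$procedure %in% c("ECT", "rTMS", "psychotherapy"), "unknown procedure")
      ok <- bad(!dt$care_level %in% registry_schemas()$procedures$levels$care_level,
                "unknown care_level")
    },
    visits = {
      ok <- bad(is.na(dt$date), "unparseable date")
      ok <- bad(is.na(dt$physician), "physician must be TRUE/FALSE")
      ok <- bad(!dt$care_level %in% registry_schemas()$visits$levels$care_level,
                "unknown care_level")
    },
    stays = {
      ok <- bad(is.na(dt$admission_date) | is.na(dt$discharge_date), "unparseable date")
      ok <- bad(dt$discharge_date < dt$admission_date, "discharge before admission")
      ok <- bad(!dt$ward %in% c("psychiatric", "non_psychiatric"), "unknown ward")
    },
    workloss = {
      ok <- bad(is.na(dt$start) | is.na(dt$end), "unparseable date")
      ok <- bad(dt$end <= dt$start, "end must be after start")
      ok <- bad(!dt$kind %in% c("sick_leave", "disability_pension"), "unknown kind")
      ok <- bad(is.na(dt$extent) | dt$extent <= 0 | dt$extent > 1,
                "extent must be in (0, 1]")
    }
  )
  attr(ok, "why") <- why
  ok
}

#' Read and validate the seven registry tables
#'
#' Reads the CSV extract, parses all dates (ISO-8601), coerces declared types
#' and enforces the row-level invariants of each schema. In strict mode any
#' violation aborts with the offending table, rule and line numbers; in
#' lenient mode offending rows are dropped with a message giving the count.
#'
#' @param dir directory containing `persons.csv`, `residency.csv`,
#'   `diagnoses.csv`, `dispensations.csv`, `procedures.csv`, `visits.csv`,
#'   `stays.csv`, `workloss.csv`; alternatively a named list/vector of file
#'   paths with those table names.
#' @param schema_strict reject files with invariant-violating rows (`TRUE`,
#'   default) or drop such rows with a logged count (`FALSE`).
#' @return a named list of `data.table`s of class `registry_tables`, sorted by
#'   person and date. Events dated outside any residency interval of their
#'   person trigger a warning (never an error).
#' @export
load_tables <- function(dir, schema_strict = TRUE) {
  schemas <- registry_schemas()
  paths <- if (is.list(dir) || length(dir) > 1L) as.list(dir)
           else as.list(setNames(file.path(dir, paste0(names(schemas), ".csv")),
                                 names(schemas)))
  missing_t <- setdiff(names(schemas), names(paths))
  if (length(missing_t)) stop("missing table paths: ", paste(missing_t, collapse = ", "))
  out <- vector("list", length(schemas))
  names(out) <- names(schemas)
  for (nm in names(schemas)) {
    path <- paths[[nm]]
    if (!file.exists(path)) stop("file not found: ", path)
    sch <- schemas[[nm]]
    dt <- data.table::fread(path, colClasses = "character", na.strings = c("", "NA"))
    miss <- setdiff(names(sch$cols), names(dt))
    if (length(miss))
      stop("table '", nm, "': missing column(s): ", paste(miss, collapse = ", "))
    dt <- dt[, names(sch$cols), with = FALSE]
    for (col in names(sch$cols)) {
      v <- dt[[col]]
      dt[, (col) := switch(sch$cols[[col]],
        character = as.character(v),
        date = parse_iso_date(v),
        integer = suppressWarnings(as.integer(v)),
        numeric = suppressWarnings(as.numeric(v)),
        logical = toupper(v) %in% "TRUE"
      )]
      if (sch$cols[[col]] == "logical")
        dt[is.na(v), (col) := NA]
    }
    keep <- table_invariants(nm, dt)
    if (!all(keep)) {
      why <- paste(attr(keep, "why"), collapse = "; ")
      if (schema_strict) {
        stop("table '", nm, "': ", sum(!keep), " invalid row(s) at line(s) ",
             paste(head(which(!keep) + 1L, 5L), collapse = ", "),
             " (", why, ")")
      }
      message("table '", nm, "': dropped ", sum(!keep), " invalid row(s) (", why, ")")
      dt <- dt[keep]
    }
    sortcols <- intersect(c("person_id", "date", "admission_date", "start"), names(dt))
    data.table::setkeyv(dt, sortcols)
    out[[nm]] <- dt
  }
  check_residency_coverage(out)
  class(out) <- c("registry_tables", "list")
  out
}

# internal: warn (never error) about events outside their person's residency
check_residency_coverage <- function(tables) {
  res <- tables$residency
  if (nrow(res) == 0L) return(invisible())
  covered <- function(pid, d) {
    idx <- res[data.table::data.table(person_id = pid, date = d),
               on = .(person_id, start <= date, end > date), which = TRUE]
    !is.na(idx)
  }
  n_out <- 0L
  for (nm in c("diagnoses", "dispensations", "procedures", "visits")) {
    dt <- tables[[nm]]
    if (nrow(dt)) n_out <- n_out + sum(!covered(dt$person_id, dt$date))
  }
  if (n_out > 0L)
    warning(n_out, " event(s) dated outside any residency interval of their person")
  invisible()
}

#' Write registry tables back to CSV
#'
#' Inverse of [load_tables()]: ISO-8601 dates, `TRUE`/`FALSE` logicals, empty
#' string for missing values, so that a load/write cycle reproduces a
#' conforming file byte-identically.
#'
#' @param tables a `registry_tables` list.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(registry_schemas())) {
    path <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(tables[[nm]], path, dateTimeAs = "ISO", logical01 = FALSE,
                       na = "", quote = FALSE, eol = "\n")
    paths[nm] <- path
  }
  invisible(paths)
}

#' Depressive events of one or all persons
#'
#' The union of events that count as activity related to depression: MDD
#' diagnoses (any care level), antidepressant dispensations, add-on medication
#' dispensations (quetiapine only when the prescribed daily dose strictly
#' exceeds the codebook threshold; dispensations without a recorded daily dose
#' never qualify as add-on), and ECT / rTMS / psychotherapy procedures.
#'
#' @param tables a `registry_tables` list.
#' @param codebook an `mdd_codebook`.
#' @param person_id optional person id (or vector); `NULL` returns all persons.
#'   Unknown persons yield zero rows.
#' @return `data.table` sorted by person and date with columns `person_id`,
#'   `date`, `event_class` (`"diagnosis"`, `"dispensation"`, `"procedure"`),
#'   `care_level` (`NA` for dispensations), `tablets` (`NA` except
#'   dispensations), `code` (ICD-10/ATC/procedure label).
#' @export
depressive_events <- function(tables, codebook, person_id = NULL) {
  dx <- tables$diagnoses[match_code(icd10, codebook$mdd)]
  dx <- dx[, .(person_id, date, event_class = "diagnosis",
               care_level, tablets = NA_integer_, code = icd10)]

  rx <- tables$dispensations
  is_ad <- match_code(rx$atc, codebook$antidepressant)
  is_addon <- match_code(rx$atc, codebook$addon_med)
  is_quet <- match_code(rx$atc, codebook$quetiapine_atc)
  # quetiapine: prescribed daily dose strictly above threshold; unknown dose excluded
  quet_ok <- !is.na(rx$daily_dose_mg) &
    rx$daily_dose_mg > codebook$quetiapine_min_daily_dose_mg
  is_addon <- is_addon & (!is_quet | quet_ok)
  rx <- rx[is_ad | is_addon]
  rx <- rx[, .(person_id, date, event_class = "dispensation",
               care_level = NA_character_, tablets, code = atc)]

  pr <- tables$procedures[, .(person_id, date, event_class = "procedure",
                              care_level, tablets = NA_integer_, code = procedure)]

  ev <- data.table::rbindlist(list(dx, rx, pr))
  if (!is.null(person_id)) {
    ids <- as.character(person_id)
    ev <- ev[ev$person_id %chin% ids]
  }
  # stable order: class rank breaks same-day ties deterministically
  ev[, `:=`(.rank = match(event_class, c("diagnosis", "dispensation", "procedure")))]
  data.table::setorderv(ev, c("person_id", "date", ".rank", "code"))
  ev[, ".rank" := NULL]
  ev[]
}
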