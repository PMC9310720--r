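#' Expand an ICD-10/ATC range expression to its constituent prefixes
#'
#' Range syntax `"F20-F29"` expands to the ten 3-character stems `F20`..`F29`;
#' a plain prefix passes through unchanged. Both endpoints must share the
#' leading letter and code length, and the numeric parts must be ordered.
#'
#' @param x character vector of prefixes and/or `"A10-A19"` style ranges.
#' @return character vector of plain prefixes.
#' @export
#' @examples
#' expand_code_range("F20-F29")
expand_code_range <- function(x) {
  out <- lapply(x, function(s) {
    if (!grepl("-", s, fixed = TRUE)) return(s)
    parts <- strsplit(s, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed code range: ", s)
    a <- parts[1]; b <- parts[2]
    la <- substr(a, 1, 1); lb <- substr(b, 1, 1)
    na <- suppressWarnings(as.integer(substr(a, 2, nchar(a))))
    nb <- suppressWarnings(as.integer(substr(b, 2, nchar(b))))
    if (la != lb || is.na(na) || is.na(nb) || nb < na || nchar(a) != nchar(b))
      stop("malformed code range: ", s)
    width <- nchar(a) - 1L
    sprintf("%s%0*d", la, width, na:nb)
  })
  unlist(out, use.names = FALSE)
}

#' Test codes against a prefix code set
#'
#' A code matches when some include prefix is a prefix of the code and no
#' exclude prefix is. This is the range/prefix semantics of registry
#' phenotyping: `"F329"` matches the set `{F32, F33}`.
#'
#' @param code character vector of ICD-10/ATC codes (non-empty strings).
#' @param code_set either a character vector of prefixes, or a list with
#'   elements `include` and optionally `exclude` (character prefixes). Range
#'   expressions are expanded.
#' @return logical vector.
#' @export
#' @examples
#' match_code("F329", c("F32", "F33"))
#' match_code("F431", list(include = "F43", exclude = "F431"))
match_code <- function(code, code_set) {
  stopifnot(is.character(code), all(nzchar(code) | is.na(code)))
  if (is.list(code_set)) {
    inc <- expand_code_range(code_set$include)
    exc <- if (!is.null(code_set$exclude)) expand_code_range(code_set$exclude) else character()
  } else {
    inc <- expand_code_range(code_set)
    exc <- character()
  }
  if (length(inc) == 0L) stop("empty code set")
  has_prefix <- function(codes, prefixes) {
    hit <- rep(FALSE, length(codes))
    for (p in prefixes) hit <- hit | startsWith(codes, p)
    hit
  }
  out <- has_prefix(code, inc)
  if (length(exc)) out <- out & !has_prefix(code, exc)
  out & !is.na(code)
}

#' Default clinical codebook
#'
#' Editable defaults mapping code prefixes to clinical concepts: the MDD
#' definition (F32/F33), the unipolarity exclusions (psychosis F20-F29, mania
#' F30, bipolar F31, dementia F00-F03), antidepressants (ATC N06A), the five
#' add-on medications (lithium, risperidone, olanzapine, aripiprazole, and
#' quetiapine at prescribed daily dose strictly above `quetiapine_min_daily_dose_mg`),
#' intentional self-harm (X60-X84), and conventional ICD-10 choices for the
#' described psychiatric and non-psychiatric comorbid conditions. Every set can
#' be overridden via [load_codebook()].
#'
#' @return a list of class `mdd_codebook`: code sets (`mdd`, `psychosis`,
#'   `mania`, `bipolar`, `dementia`, `antidepressant`, `addon_med`,
#'   `self_harm`), `comorbidities` (named list of code sets; psychiatric ones
#'   flagged in `psychiatric_comorbidities`), and `quetiapine_min_daily_dose_mg`.
#' @export
default_codebook <- function() {
  cb <- list(
    mdd = c("F32", "F33"),
    psychosis = "F20-F29",
    mania = "F30",
    bipolar = "F31",
    dementia = "F00-F03",
    antidepressant = "N06A",
    # ATC codes: lithium, olanzapine, quetiapine, risperidone, aripiprazole
    addon_med = c("N05AN01", "N05AH03", "N05AH04", "N05AX08", "N05AX12"),
    quetiapine_atc = "N05AH04",
    quetiapine_min_daily_dose_mg = 100,
    self_harm = "X60-X84",
    comorbidities = list(
      anxiety = "F40-F41",
      stress = list(include = "F43", exclude = "F431"),
      sleep = c("F51", "G47"),
      substance = "F10-F19",
      alcohol = "F10",
      ocd = "F42",
      hyperkinetic = "F90",
      autism = "F84",
      personality = c("F60", "F61"),
      self_harm = "X60-X84",
      cardiovascular = c("I20-I25", "I60-I69"),
      hypertension = "I10-I15",
      diabetes_t2 = "E11",
      hypothyroidism = "E03",
      ibd = c("K50", "K51"),
      ra = c("M05", "M06")
    ),
    psychiatric_comorbidities = c(
      "anxiety", "stress", "sleep", "substance", "alcohol", "ocd",
      "hyperkinetic", "autism", "personality", "self_harm"
    )
  )
  class(cb) <- "mdd_codebook"
  validate_codebook(cb)
}

#' Load a codebook from YAML, overriding the defaults
#'
#' The YAML file may redefine any subset of the default code sets (range
#' syntax `"F20-F29"` allowed, `include`/`exclude` lists allowed) and the
#' quetiapine dose threshold; unspecified entries keep their defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return an `mdd_codebook` list.
#' @export
#' @examples
#' load_codebook(system.file("extdata", "codebook.yaml", package = "mddburden"))
load_codebook <- function(path = NULL) {
  cb <- unclass(default_codebook())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("codebook file not found: ", path)
    user <- yaml::read_yaml(path)
    for (nm in names(user)) {
      if (nm == "comorbidities") {
        for (cnm in names(user$comorbidities)) cb$comorbidities[[cnm]] <- user$comorbidities[[cnm]]
      } else cb[[nm]] <- user[[nm]]
    }
  }
  class(cb) <- "mdd_codebook"
  validate_codebook(cb)
}

# internal: structural invariants of a codebook
validate_codebook <- function(cb) {
  core <- c("mdd", "psychosis", "mania", "bipolar", "dementia",
            "antidepressant", "addon_med", "self_harm")
  for (nm in core) {
    set <- cb[[nm]]
    inc <- if (is.list(set)) set$include else set
    if (length(inc) == 0L) stop("codebook set '", nm, "' is empty")
  }
  # the MDD definition must be disjoint from the exclusion diagnoses
  mdd <- expand_code_range(cb$mdd)
  for (nm in c("psychosis", "mania", "bipolar", "dementia")) {
    exc <- expand_code_range(if (is.list(cb[[nm]])) cb[[nm]]$include else cb[[nm]])
    for (a in mdd) for (b in exc) {
      if (startsWith(a, b) || startsWith(b, a))
        stop("codebook: mdd set overlaps exclusion set '", nm, "'")
    }
  }
  cb
}
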