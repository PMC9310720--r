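#' Round half away from zero
#'
#' Presentation rounding used for reported ratios and percentages: ties go up
#' (`round_half_up(2.25, 1)` is 2.3), unlike base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(7.90 / 2.48, 1)  # 3.2
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count, rounded for presentation
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places (default 1).
#' @return percentage on the 0-100 scale, rounded half-up.
#' @export
#' @examples
#' pct(87071, 137822)  # 63.2
pct <- function(num, den, digits = 1) {
  stopifnot(den > 0)
  round_half_up(100 * num / den, digits)
}

# --- calendar helpers (base Date arithmetic; no times of day anywhere) -----

#' First day of the calendar month containing a date
#' @param d Date vector.
#' @return Date vector of month starts.
#' @export
month_start <- function(d) {
  if (length(d) == 0L) return(as.Date(d))
  lt <- as.POSIXlt(d)
  lt$mday <- 1L
  as.Date(lt)
}

#' Shift a month-start date by whole calendar months
#' @param d Date vector of month starts.
#' @param k integer vector of month offsets (recycled).
#' @return Date vector.
#' @export
add_months <- function(d, k) {
  if (length(d) == 0L) return(as.Date(d))
  lt <- as.POSIXlt(d)
  mon <- lt$year * 12L + lt$mon + as.integer(k)
  as.Date(sprintf("%04d-%02d-01", mon %/% 12L + 1900L, mon %% 12L + 1L))
}

#' Signed whole-month distance between two dates' calendar months
#' @param d Date vector.
#' @param ref Date vector of reference dates (recycled).
#' @return integer vector: calendar month of `d` minus calendar month of `ref`.
#' @export
month_diff <- function(d, ref) {
  a <- as.POSIXlt(d); b <- as.POSIXlt(ref)
  (a$year * 12L + a$mon) - (b$year * 12L + b$mon)
}

#' Overlap in days between a half-open interval and a half-open window
#'
#' All registry intervals are half-open `[start, end)`; a one-day event is
#' `[d, d + 1)`.
#'
#' @param s,e interval start/end (Date or numeric day).
#' @param ws,we window start/end.
#' @return numeric vector of overlap days (>= 0).
#' @export
overlap_days <- function(s, e, ws, we) {
  pmax(0, as.numeric(pmin(e, we)) - as.numeric(pmax(s, ws)))
}

z975 <- 1.959964

# internal: parse ISO dates strictly, returning NA for malformed strings
parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}
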