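# All-cause mortality: survival records from the matched cohort and a
# single-binary-covariate Cox proportional-hazards fit by Newton-Raphson
# maximization of the partial likelihood (Breslow or Efron ties).

#' Survival records for the matched cohort
#'
#' One record per followed individual: days from index to death or censoring
#' (emigration, post-index exclusion diagnosis, or end of data), with
#' zero-length follow-up clamped to half a day rather than dropped.
#'
#' @param cohort `members` table of [build_cohort()] (cases and controls, each
#'   with `follow_up_end` and `reason` from the shared censoring rules).
#' @return `data.table`: `person_id`, `group`, `pair_id`, `time` (days),
#'   `event` (death).
#' @export
survival_table <- function(cohort) {
  out <- cohort[, .(person_id, group, pair_id,
                    time = pmax(as.numeric(follow_up_end - index_date), 0.5),
                    event = reason == "death")]
  data.table::setorderv(out, c("pair_id", "group"))
  out[]
}

#' Cox proportional-hazards fit for a binary group contrast
#'
#' Newton-Raphson maximization of the partial likelihood with Breslow or
#' Efron handling of tied event times; convergence when the log-likelihood
#' changes by less than 1e-9 (at most 50 iterations). With all events in one
#' group the likelihood is monotone and the estimate is flagged non-finite.
#'
#' @param records table with `time`, `event`, and `group` (the level equal to
#'   `exposed` codes 1).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param exposed label of the exposed group (default `"mdd"`).
#' @return list of class `cox_fit`: `log_hr`, `se_log_hr`, `hr`, `ci95`, `n`,
#'   `n_events`, `ties`, `iter`, `converged`.
#' @export
fit_cox <- function(records, ties = c("efron", "breslow"), exposed = "mdd") {
  ties <- match.arg(ties)
  x <- as.numeric(records$group == exposed)
  tt <- as.numeric(records$time)
  dd <- as.logical(records$event)
  if (!any(dd)) stop("no events: Cox model undefined")
  if (all(x[dd] == 1) || all(x[dd] == 0)) {
    out <- list(log_hr = NA_real_, se_log_hr = NA_real_, hr = NA_real_,
                ci95 = c(NA_real_, NA_real_), n = length(tt), n_events = sum(dd),
                ties = ties, iter = 0L, converged = FALSE,
                note = "monotone likelihood: all events in one group")
    class(out) <- "cox_fit"
    return(out)
  }

  # risk-set counts per unique event time: n1 = exposed at risk, n0 = rest
  et <- sort(unique(tt[dd]))
  st <- sort(tt)
  st1 <- sort(tt[x == 1])
  n_ge <- function(sorted, v) length(sorted) - findInterval(v, sorted, left.open = TRUE)
  nr <- n_ge(st, et)
  nr1 <- n_ge(st1, et)
  nr0 <- nr - nr1
  # tied-event counts per event time
  dtab <- data.table::data.table(t = tt[dd], x1 = x[dd])[, .(d = .N, d1 = sum(x1)), keyby = t]
  d <- dtab$d; d1 <- dtab$d1

  loglik <- function(beta) {
    eb <- exp(beta)
    if (ties == "breslow") {
      s0 <- nr0 + nr1 * eb
      ll <- sum(d1 * beta - d * log(s0))
      s1 <- nr1 * eb
      u <- sum(d1 - d * s1 / s0)
      i <- sum(d * (s1 / s0) * (1 - s1 / s0))
    } else {
      # Efron: within a tie of size d, subtract k/d of the tied group's sums
      reps <- rep(seq_along(d), d)
      k <- unlist(lapply(d, function(di) seq_len(di) - 1L))
      s0 <- (nr0[reps] + nr1[reps] * eb) - (k / d[reps]) * ((d[reps] - d1[reps]) + d1[reps] * eb)
      s1 <- nr1[reps] * eb - (k / d[reps]) * d1[reps] * eb
      ll <- sum(d1 * beta) - sum(log(s0))
      u <- sum(d1) - sum(s1 / s0)
      i <- sum((s1 / s0) * (1 - s1 / s0))
    }
    list(ll = ll, u = u, i = i)
  }

  beta <- 0
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(50L)) {
    cur <- loglik(beta)
    if (abs(cur$ll - ll_old) < 1e-9 && it > 1L) { converged <- TRUE; break }
    ll_old <- cur$ll
    step <- cur$u / cur$i
    step <- sign(step) * min(abs(step), 5)  # damp wild early steps
    beta <- beta + step
  }
  info <- loglik(beta)$i
  se <- sqrt(1 / info)
  out <- list(log_hr = beta, se_log_hr = se, hr = exp(beta),
              ci95 = exp(beta + c(-1, 1) * z975 * se),
              n = length(tt), n_events = sum(dd), ties = ties,
              iter = it, converged = converged)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n = %d, events = %d\n", x$ties, x$n, x$n_events))
  if (is.finite(x$log_hr))
    cat(sprintf("HR %.2f (95%% CI: %.2f-%.2f), log HR %.4f (SE %.4f)\n",
                x$hr, x$ci95[1], x$ci95[2], x$log_hr, x$se_log_hr))
  else cat("estimate non-finite:", x$note, "\n")
  invisible(x)
}

#' All-cause mortality rate
#'
#' Deaths per 1000 person-years at risk, overall or per group.
#'
#' @param records output of [survival_table()].
#' @param by_group also return per-group rates (default `TRUE`).
#' @return `data.table`: `group` (including `"all"`), `deaths`,
#'   `person_years`, `rate_per_1000py`.
#' @export
mortality_rate <- function(records, by_group = TRUE) {
  calc <- function(r, label) {
    py <- sum(r$time) / 365.25
    if (py <= 0) stop("no follow-up time")
    data.table::data.table(group = label, deaths = sum(r$event),
                           person_years = py,
                           rate_per_1000py = 1000 * sum(r$event) / py)
  }
  out <- calc(records, "all")
  if (by_group) {
    per <- records[, .(deaths = sum(event), person_years = sum(time) / 365.25),
                   by = group]
    per[, rate_per_1000py := 1000 * deaths / person_years]
    out <- data.table::rbindlist(list(out, per), use.names = TRUE)
  }
  out[]
}
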