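# Synthetic registry generator
#
# Emits the seven registry tables with the statistical structure the pipeline
# assumes (latent MDD onsets, episode-shaped event streams, matched-control
# material, censoring processes) plus a ground-truth table for recovery tests.
# All randomness flows through counter-based per-person substreams
# (hash_unif), so the scalar seed fully determines the output and adding
# persons never perturbs the draws of existing ones.

#' Simulation configuration
#'
#' Defaults encode the study conditions the analysis targets: a 2010-2019 data
#' window with a 2012-2019 inclusion window, 63.2% women among onsets, index
#' care-level mix 68.2/27.3/4.6 (primary/psychiatric/other), log-normal true
#' episode duration with median 398 days, control baseline mortality 5.4 per
#' 1000 person-years with a case log-hazard increment of log(2.2) (their
#' pooled rate is then about 8.6 per 1000 person-years), pre-index
#' antidepressant use among treated cases calibrated to about 26% of cases,
#' and a 13.8% primary-to-psychiatric referral propensity in the first year.
#'
#' @param seed integer; the single source of randomness.
#' @param n_persons number of simulated persons.
#' @param ... overrides for any default listed in the function body (rates per
#'   year unless the name says otherwise; durations in days).
#' @return a list of class `mdd_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_persons = 10000L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_persons = as.integer(n_persons),
    window = c("2010-01-01", "2019-01-01"),
    inclusion_window = c("2012-01-01", "2019-01-01"),
    # population structure
    sex_ratio_population = 0.5,
    age_mean = 41.3, age_sd = 19.4, age_min = 12, age_max = 94,
    age_ref_date = "2015-01-01",
    n_municipalities = 10L,
    p_immigrant = 0.08,
    emigration_rate_per_year = 0.02,
    # latent disease model
    annual_mdd_onset_rate = 0.0082,
    sex_ratio_cases = 0.632,
    care_level_mix = c(primary = 0.682, psychiatric = 0.273, other = 0.046),
    p_inpatient_at_psych_index = 0.10,
    episode_median_days = 398, episode_sigma = 0.6,
    dx_gap_mean_days = 120, dx_gap_min_days = 7, dx_gap_max_days = 350,
    p_renewal_dx_same_level = 0.92,
    # antidepressant therapy
    treatment_propensities = list(ad = 0.78, addon = 0.015,
                                  psychotherapy = 0.25, ect = 0.015, rtms = 0.008),
    p_pre_ad = 0.33, pre_ad_mean_days = 150,
    ad_delay_mean_days = 10,
    ad_duration_median_days = 180, ad_duration_sigma = 0.8,
    dispensation_interval_days = 90L,
    tablets_per_fill = 100L,
    psy_gap_mean_days = 21, psy_span_days = 180,
    # comorbid conditions: background onset rate (per year, everyone), extra
    # case probability with an exponential pre-onset ramp, representative code
    comorbidities = list(
      anxiety       = list(bg = 0.0050, extra = 0.200, icd10 = "F411"),
      stress        = list(bg = 0.0060, extra = 0.150, icd10 = "F432"),
      sleep         = list(bg = 0.0060, extra = 0.100, icd10 = "F510"),
      substance     = list(bg = 0.0015, extra = 0.040, icd10 = "F19"),
      alcohol       = list(bg = 0.0010, extra = 0.030, icd10 = "F102"),
      ocd           = list(bg = 0.0003, extra = 0.012, icd10 = "F42"),
      hyperkinetic  = list(bg = 0.0020, extra = 0.025, icd10 = "F900"),
      autism        = list(bg = 0.0006, extra = 0.010, icd10 = "F840"),
      personality   = list(bg = 0.0001, extra = 0.007, icd10 = "F609"),
      self_harm     = list(bg = 0.0002, extra = 0.012, icd10 = "X60"),
      cardiovascular= list(bg = 0.0100, extra = 0.030, icd10 = "I209"),
      hypertension  = list(bg = 0.0200, extra = 0.030, icd10 = "I10"),
      diabetes_t2   = list(bg = 0.0050, extra = 0.010, icd10 = "E11"),
      hypothyroidism= list(bg = 0.0070, extra = 0.015, icd10 = "E039"),
      ibd           = list(bg = 0.0015, extra = 0.003, icd10 = "K50"),
      ra            = list(bg = 0.0010, extra = 0.002, icd10 = "M059")
    ),
    comorbidity_ramp_mean_days = 365,
    exclusion_dx_rate_per_year = 0.002,
    # mortality
    baseline_mortality_per_1000py = 5.4,
    case_log_hr = log(2.2),
    # healthcare utilization (physician-visit rates per year)
    visit_rates = list(base = 2.5, case_pre = 5.7, case_post = 7.9),
    visit_level_mix = list(base = c(primary = 0.56, psychiatric = 0.01, other = 0.43),
                           case = c(primary = 0.55, psychiatric = 0.25, other = 0.20)),
    nurse_visit_rate_per_month = 0.08,
    stay_model = list(base_rate = 0.06, base_los_median = 5, base_los_sigma = 0.7,
                      case_psych_pre = 0.025, case_psych_post = 0.10,
                      psych_los_median = 10, psych_los_sigma = 0.6,
                      case_nonpsych_pre = 0.13, case_nonpsych_post = 0.15,
                      nonpsych_los_median = 7, nonpsych_los_sigma = 0.7),
    # work loss (spells; ages 20-64 at spell start)
    workloss_model = list(sick_base_rate = 0.12, sick_base_median = 20,
                          sick_case_pre_rate = 0.45, sick_case_pre_median = 30,
                          sick_case_post_rate = 0.90, sick_case_post_median = 45,
                          sick_sigma = 0.9, p_extent_full = 0.8,
                          dp_p_case = 0.045, dp_p_control = 0.018,
                          dp_p_extent_full = 0.6),
    # referral flow
    referral_propensity = 0.138,
    # nuisance streams exercising the codebook filters
    p_bg_psychotherapy = 0.02,
    p_pop_ad = 0.05,
    noise_fill_rate_per_year = 0.5,
    p_quetiapine_low_dose = 0.004
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) && nm != "comorbidities") {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_persons >= 0L,
            cfg$annual_mdd_onset_rate >= 0,
            cfg$emigration_rate_per_year >= 0,
            cfg$baseline_mortality_per_1000py >= 0,
            cfg$episode_median_days > 0,
            all(unlist(cfg$treatment_propensities) >= 0),
            all(unlist(cfg$treatment_propensities) <= 1))
  s <- sum(cfg$care_level_mix)
  if (abs(s - 1) > 0.02) stop("care_level_mix must sum to 1")
  cfg$care_level_mix <- cfg$care_level_mix / s
  for (nm in names(cfg$visit_level_mix))
    cfg$visit_level_mix[[nm]] <- cfg$visit_level_mix[[nm]] / sum(cfg$visit_level_mix[[nm]])
  class(cfg) <- "mdd_sim_config"
  cfg
}

# --- inverse-CDF helpers on hashed uniforms --------------------------------

qexp_u <- function(u, rate) -log(u) / rate

qexp_trunc <- function(u, mean, lo, hi) {
  r <- 1 / mean
  lo + (-log(1 - u * (1 - exp(-r * (hi - lo)))) / r)
}

qnorm_trunc <- function(u, mean, sd, lo, hi) {
  pa <- stats::pnorm(lo, mean, sd); pb <- stats::pnorm(hi, mean, sd)
  stats::qnorm(pa + u * (pb - pa), mean, sd)
}

pick <- function(u, probs, labels) {
  labels[findInterval(u, cumsum(probs / sum(probs)), left.open = TRUE) + 1L]
}

#' Generate synthetic registry tables and their ground truth
#'
#' @param config an `mdd_sim_config` from [sim_config()].
#' @return list with `tables` (a `registry_tables` list, as from
#'   [load_tables()]), `truth` (one row per latent MDD onset: onset date, true
#'   episode interval, hazard multiplier, treatment flags), and `config`.
#' @export
generate_registry <- function(config = sim_config()) {
  stopifnot(inherits(config, "mdd_sim_config"))
  cfg <- config
  seed <- cfg$seed
  n <- cfg$n_persons
  w0 <- as.Date(cfg$window[1]); w1 <- as.Date(cfg$window[2])
  w0n <- as.numeric(w0); w1n <- as.numeric(w1)
  span <- w1n - w0n

  if (n == 0L) {
    tabs <- empty_tables()
    return(list(tables = tabs, truth = empty_truth(), config = cfg))
  }

  idx <- seq_len(n)
  ru <- function(ids, ctr) hash_unif(seed, ids, ctr)
  U <- function(ctr) ru(idx, ctr)

  ## ---- persons, residency, latent onset, death ---------------------------
  P <- data.table::data.table(id = idx)
  P[, sex := ifelse(U(1) < cfg$sex_ratio_population, "F", "M")]
  refn <- as.numeric(as.Date(cfg$age_ref_date))
  P[, birth := round(refn - qnorm_trunc(U(2), cfg$age_mean, cfg$age_sd,
                                        cfg$age_min, cfg$age_max) * 365.25)]
  muni_w <- 1 / seq_len(cfg$n_municipalities)
  P[, municipality := pick(U(3), muni_w, sprintf("M%02d", seq_len(cfg$n_municipalities)))]
  P[, res_start := ifelse(U(4) < cfg$p_immigrant,
                          w0n + floor(U(5) * span * 0.85), w0n)]
  P[, res_end := pmin(w1n, P$res_start +
                        ceiling(qexp_u(U(6), cfg$emigration_rate_per_year / 365.25)))]

  # sex-specific onset hazard so that the configured share of onsets is female
  years <- span / 365.25
  rate_sex <- cfg$annual_mdd_onset_rate * 2 *
    ifelse(P$sex == "F", cfg$sex_ratio_cases, 1 - cfg$sex_ratio_cases)
  P[, onset_flag := U(7) < (1 - exp(-rate_sex * years))]
  P[, onset := w0n + floor(U(8) * span)]
  P[, dur := pmax(1, round(qlnorm(U(9), log(cfg$episode_median_days), cfg$episode_sigma)))]

  lam0 <- cfg$baseline_mortality_per_1000py / 1000 / 365.25
  clock0 <- pmax(w0n, P$res_start)
  t1 <- clock0 + qexp_u(U(10), lam0)
  P[, is_case := onset_flag & onset >= res_start & onset < res_end & t1 > onset]
  t2 <- P$onset + qexp_u(U(11), lam0 * exp(cfg$case_log_hr))
  P[, death := ifelse(is_case, t2, t1)]
  # registry sees the death only while resident and inside the window
  P[, death_rec := ifelse(death < pmin(res_end, w1n), round(death), NA_real_)]
  # hard end of any emitted event stream
  P[, ev_end := pmin(death, res_end, w1n)]

  cases <- P[is_case == TRUE]
  ids <- cases$id

  ## ---- index diagnosis and care level ------------------------------------
  mix <- cfg$care_level_mix
  cases[, lvl3 := pick(ru(id, 36), mix, c("primary", "psychiatric", "other"))]
  cases[, care_index := data.table::fifelse(
    lvl3 == "psychiatric",
    ifelse(ru(id, 37) < cfg$p_inpatient_at_psych_index,
           "psychiatric_inpatient", "psychiatric_outpatient"),
    ifelse(lvl3 == "primary", "primary", "other"))]

  dx_list <- list()
  rx_list <- list()
  pr_list <- list()

  if (nrow(cases)) {
    dx_list$index <- cases[, .(id, date = onset, icd10 = ifelse(ru(id, 38) < 0.8, "F329", "F339"),
                               care_level = care_index)]

    ## ---- renewal MDD diagnoses inside the true episode + terminal contact --
    K <- 70L
    rn <- cases[rep(seq_len(.N), each = K)][, j := rep(seq_len(K) - 1L, times = nrow(cases))]
    rn[, gap := qexp_trunc(ru(id, 100 + j), cfg$dx_gap_mean_days,
                           cfg$dx_gap_min_days, cfg$dx_gap_max_days)]
    rn[, t := round(cumsum(gap)), by = id]
    rn <- rn[t < dur]
    term <- cases[, .(id, onset, dur, lvl3, j = K)]
    rn <- data.table::rbindlist(list(rn[, .(id, onset, dur, lvl3, j, t)],
                                     term[, .(id, onset, dur, lvl3, j, t = dur)]),
                                use.names = TRUE)
    # care level of follow-up diagnoses stays off the psychiatric level for
    # non-referred primary-index cases so the referral share is controlled
    usame <- ru(rn$id, 1100 + rn$j)
    rn[, care_level := data.table::fcase(
      lvl3 == "primary", ifelse(usame < cfg$p_renewal_dx_same_level, "primary", "other"),
      lvl3 == "psychiatric", ifelse(usame < 0.9, "psychiatric_outpatient", "primary"),
      default = "other")]
    rn[lvl3 == "psychiatric" & care_level == "psychiatric_outpatient" &
         ru(id, 1200 + j) < 0.08, care_level := "psychiatric_inpatient"]
    dx_list$renewal <- rn[, .(id, date = onset + t,
                              icd10 = ifelse(ru(id, 1300 + j) < 0.7, "F329", "F339"),
                              care_level)]

    ## ---- first-year referral to psychiatric care (primary-index cases) ----
    refc <- cases[lvl3 == "primary" & ru(id, 26) < cfg$referral_propensity]
    if (nrow(refc))
      dx_list$referral <- refc[, .(id, date = onset + 1 + floor(ru(id, 27) * 364),
                                   icd10 = "F329", care_level = "psychiatric_outpatient")]

    ## ---- antidepressant dispensations --------------------------------------
    tp <- cfg$treatment_propensities
    adc <- cases[ru(id, 12) < tp$ad]
    if (nrow(adc)) {
      adc[, pre := ru(id, 14) < cfg$p_pre_ad]
      adc[, ad_start := ifelse(pre,
        onset - round(qexp_trunc(ru(id, 15), cfg$pre_ad_mean_days, 10, 360)),
        onset + round(pmin(qexp_u(ru(id, 13), 1 / cfg$ad_delay_mean_days),
                           pmax(dur - 1, 0))))]
      adc[, ad_stop := onset + pmin(dur, round(qlnorm(ru(id, 16),
        log(cfg$ad_duration_median_days), cfg$ad_duration_sigma)))]
      adc[, atc := pick(ru(id, 50), rep(0.2, 5),
                        c("N06AB10", "N06AB04", "N06AB06", "N06AX16", "N06AA09"))]
      KF <- 40L
      fills <- adc[rep(seq_len(.N), each = KF)][, j := rep(seq_len(KF) - 1L, times = nrow(adc))]
      fills <- fills[, date := ad_start + j * cfg$dispensation_interval_days][date <= ad_stop]
      rx_list$ad <- fills[, .(id, date, atc, tablets = cfg$tablets_per_fill,
                              daily_dose_mg = NA_real_)]
      ad_truth <- adc[, .(id, ad_start, ad_stop)]
    } else ad_truth <- data.table::data.table(id = integer(), ad_start = numeric(), ad_stop = numeric())

    ## ---- add-on medication --------------------------------------------------
    aoc <- cases[ru(id, 20) < tp$addon]
    if (nrow(aoc)) {
      aoc[, atc := pick(ru(id, 21), rep(0.2, 5),
                        c("N05AN01", "N05AH03", "N05AH04", "N05AX08", "N05AX12"))]
      aoc[, ao_start := onset + round(pmin(qexp_u(ru(id, 22), 1 / 60), pmax(dur - 1, 0)))]
      KA <- 20L
      af <- aoc[rep(seq_len(.N), each = KA)][, j := rep(seq_len(KA) - 1L, times = nrow(aoc))]
      af <- af[, date := ao_start + j * cfg$dispensation_interval_days][date <= onset + dur]
      rx_list$addon <- af[, .(id, date, atc,
                              tablets = cfg$tablets_per_fill,
                              daily_dose_mg = ifelse(atc == "N05AH04", 300, NA_real_))]
    }

    ## ---- procedures ---------------------------------------------------------
    psc <- cases[ru(id, 17) < tp$psychotherapy]
    if (nrow(psc)) {
      psc[, t0 := round(qexp_u(ru(id, 35), 1 / 20))]
      KP <- 30L
      ss <- psc[rep(seq_len(.N), each = KP)][, j := rep(seq_len(KP) - 1L, times = nrow(psc))]
      ss[, gap := qexp_u(ru(id, 240 + j), 1 / cfg$psy_gap_mean_days)]
      ss[, t := t0 + round(cumsum(gap)), by = id]
      ss <- ss[t < pmin(dur, t0 + cfg$psy_span_days)]
      ss[, care_level := data.table::fcase(lvl3 == "primary", "primary",
                                           lvl3 == "psychiatric", "psychiatric_outpatient",
                                           default = "other")]
      pr_list$psy <- ss[, .(id, date = onset + t, procedure = "psychotherapy", care_level)]
    }
    ect <- cases[lvl3 == "psychiatric" & ru(id, 18) < tp$ect]
    if (nrow(ect)) {
      es <- ect[rep(seq_len(.N), each = 6L)][, j := rep(0:5, times = nrow(ect))]
      pr_list$ect <- es[, .(id, date = onset + 7 + 3 * j, procedure = "ECT",
                            care_level = "psychiatric_inpatient")]
    }
    rtm <- cases[lvl3 == "psychiatric" & ru(id, 19) < tp$rtms]
    if (nrow(rtm)) {
      rs <- rtm[rep(seq_len(.N), each = 10L)][, j := rep(0:9, times = nrow(rtm))]
      pr_list$rtms <- rs[, .(id, date = onset + 14 + 2 * j, procedure = "rTMS",
                             care_level = "psychiatric_outpatient")]
    }
  } else {
    ad_truth <- data.table::data.table(id = integer(), ad_start = numeric(), ad_stop = numeric())
  }

  ## ---- comorbid-condition diagnoses (everyone; cases get a pre-onset ramp) --
  cm_list <- list()
  onset_of <- P$onset; is_c <- P$is_case
  for (ci in seq_along(cfg$comorbidities)) {
    par <- cfg$comorbidities[[ci]]
    tbg <- clock0 + qexp_u(U(500 + 3 * ci), par$bg / 365.25)
    keep <- tbg < P$ev_end
    rows <- data.table::data.table(id = idx[keep], date = round(tbg[keep]),
                                   icd10 = par$icd10, care_level = "primary")
    sel <- is_c & (U(501 + 3 * ci) < par$extra)
    off <- round(qexp_u(U(502 + 3 * ci), 1 / cfg$comorbidity_ramp_mean_days))
    dex <- onset_of - off
    keep2 <- sel & dex >= P$res_start & dex >= w0n
    rows2 <- data.table::data.table(id = idx[keep2], date = dex[keep2],
                                    icd10 = par$icd10, care_level = "primary")
    cm_list[[ci]] <- data.table::rbindlist(list(rows, rows2))
  }
  cm <- data.table::rbindlist(cm_list)
  cm[icd10 == "X60", care_level := "other"]
  dx_list$comorbidity <- cm

  ## ---- exclusion diagnoses (psychosis/bipolar/mania/dementia) --------------
  tex <- clock0 + qexp_u(U(31), cfg$exclusion_dx_rate_per_year / 365.25)
  keep <- tex < P$ev_end
  if (any(keep)) {
    dx_list$exclusion <- data.table::data.table(
      id = idx[keep], date = round(tex[keep]),
      icd10 = pick(U(32)[keep], c(0.30, 0.40, 0.05, 0.25),
                   c("F200", "F31", "F300", "F03")),
      care_level = "psychiatric_outpatient")
  }

  ## ---- nuisance dispensations & procedures ---------------------------------
  quet <- which(U(33) < cfg$p_quetiapine_low_dose)
  if (length(quet))
    rx_list$quet_low <- data.table::data.table(
      id = quet, date = w0n + floor(ru(quet, 34) * span),
      atc = "N05AH04", tablets = 30L, daily_dose_mg = 50)
  popad <- which(!is_c & U(28) < cfg$p_pop_ad)
  if (length(popad)) {
    st <- w0n + floor(ru(popad, 29) * span)
    du <- qexp_u(ru(popad, 30), 1 / 365)
    KD <- 20L
    pa <- data.table::data.table(id = rep(popad, each = KD),
                                 st = rep(st, each = KD), du = rep(du, each = KD),
                                 j = rep(seq_len(KD) - 1L, times = length(popad)))
    pa <- pa[, date := st + j * cfg$dispensation_interval_days][date <= st + du]
    rx_list$popad <- pa[, .(id, date, atc = "N06AB04",
                            tablets = cfg$tablets_per_fill, daily_dose_mg = NA_real_)]
  }
  bgp <- which(U(39) < cfg$p_bg_psychotherapy)
  if (length(bgp))
    pr_list$bg_psy <- data.table::data.table(
      id = bgp, date = w0n + floor(ru(bgp, 43) * span),
      procedure = "psychotherapy", care_level = "primary")

  ## ---- yearly grids: noise fills, stays, work-loss spells ------------------
  ny <- ceiling(span / 365)
  yg <- data.table::CJ(id = idx, y = seq_len(ny) - 1L)
  yg <- merge(yg, P[, .(id, res_start, res_end, ev_end, onset, dur, is_case, birth)], by = "id")
  yg[, `:=`(ys = w0n + y * 365, ye = pmin(w0n + (y + 1L) * 365, w1n))]
  yg[, avail := pmax(0, pmin(ye, ev_end) - pmax(ys, res_start))]
  yg[, pre_ov := ifelse(is_case, overlap_days(pmax(ys, res_start), pmin(ye, ev_end),
                                              onset - 365, onset), 0)]
  yg[, post_ov := ifelse(is_case, overlap_days(pmax(ys, res_start), pmin(ye, ev_end),
                                               onset, onset + dur), 0)]

  # noise dispensations (non-psychiatric ATC) for everyone
  yg[, ncnt := pmin(qpois(hash_unif(seed, id, 70000 + y),
                          cfg$noise_fill_rate_per_year * avail / 365), 3L)]
  nf <- yg[ncnt > 0][rep(seq_len(.N), ncnt)][, k := data.table::rowid(id, y)]
  if (nrow(nf)) {
    nf[, date := pmax(ys, res_start) + floor(hash_unif(seed, id, 71000 + y * 4 + k) *
                                               pmax(avail, 1))]
    rx_list$noise <- nf[, .(id, date,
                            atc = pick(hash_unif(seed, id, 72000 + y * 4 + k),
                                       c(0.4, 0.3, 0.3), c("C07AB02", "A02BC02", "C10AA05")),
                            tablets = 100L, daily_dose_mg = NA_real_)]
  }

  stays <- sim_stays(yg, cfg, seed)
  workloss <- sim_workloss(yg, cfg, seed)
  visits <- sim_visits(P, cfg, seed, w0, w1)

  ## ---- assemble ------------------------------------------------------------
  pid <- function(i) sprintf("P%06d", i)
  num2date <- function(x) as.Date(x, origin = "1970-01-01")

  clip_events <- function(dt, proto) {
    if (is.null(dt) || ncol(dt) == 0L || nrow(dt) == 0L) return(proto)
    dt <- merge(dt, P[, .(id, res_start, ev_end)], by = "id")
    dt <- dt[date >= pmax(res_start, w0n) & date < ev_end]
    dt[, c("res_start", "ev_end") := NULL]
    dt
  }
  proto_dx <- data.table::data.table(id = integer(), date = numeric(),
                                     icd10 = character(), care_level = character())
  proto_rx <- data.table::data.table(id = integer(), date = numeric(),
                                     atc = character(), tablets = integer(),
                                     daily_dose_mg = numeric())
  proto_pr <- data.table::data.table(id = integer(), date = numeric(),
                                     procedure = character(), care_level = character())

  dx <- clip_events(data.table::rbindlist(dx_list, use.names = TRUE, fill = TRUE), proto_dx)
  rx <- clip_events(data.table::rbindlist(rx_list, use.names = TRUE, fill = TRUE), proto_rx)
  pr <- clip_events(data.table::rbindlist(pr_list, use.names = TRUE, fill = TRUE), proto_pr)

  tabs <- list(
    persons = P[, .(person_id = pid(id), sex, birth_date = num2date(birth),
                    municipality, death_date = num2date(death_rec))],
    residency = P[, .(person_id = pid(id), start = num2date(res_start),
                      end = num2date(res_end))],
    diagnoses = dx[, .(person_id = pid(id), date = num2date(date), icd10, care_level)],
    dispensations = rx[, .(person_id = pid(id), date = num2date(date), atc,
                           tablets = as.integer(tablets), daily_dose_mg)],
    procedures = pr[, .(person_id = pid(id), date = num2date(date), procedure, care_level)],
    visits = visits[, .(person_id = pid(id), date = num2date(date), care_level, physician)],
    stays = stays[, .(person_id = pid(id), admission_date = num2date(adm),
                      discharge_date = num2date(dis), ward)],
    workloss = workloss[, .(person_id = pid(id), start = num2date(s),
                            end = num2date(e), kind, extent)]
  )
  for (nm in names(tabs)) {
    sortcols <- intersect(c("person_id", "date", "admission_date", "start"),
                          names(tabs[[nm]]))
    data.table::setkeyv(tabs[[nm]], sortcols)
  }
  class(tabs) <- c("registry_tables", "list")

  truth <- P[is_case == TRUE, .(id, onset, dur)]
  truth <- merge(truth, cases[, .(id, care_index, lvl3)], by = "id")
  truth <- merge(truth, ad_truth, by = "id", all.x = TRUE)
  truth <- truth[, .(person_id = pid(id), onset_date = num2date(onset),
                     true_end = num2date(onset + dur), true_duration_days = dur,
                     hazard_mult = exp(cfg$case_log_hr),
                     care_level_at_onset = lvl3,
                     ad_start = num2date(ad_start), ad_stop = num2date(ad_stop))]
  data.table::setkeyv(truth, "person_id")

  list(tables = tabs, truth = truth, config = cfg)
}

# inpatient stays: a background non-psychiatric process plus case-phase
# (pre-onset year / in-episode) psychiatric and non-psychiatric processes
sim_stays <- function(yg, cfg, seed) {
  sm <- cfg$stay_model
  procs <- list(
    list(tag = 0L, rate_col = "avail", rate = sm$base_rate, ward = "non_psychiatric",
         losm = sm$base_los_median, loss = sm$base_los_sigma),
    list(tag = 1L, rate_col = "pre_ov", rate = sm$case_psych_pre, ward = "psychiatric",
         losm = sm$psych_los_median, loss = sm$psych_los_sigma),
    list(tag = 2L, rate_col = "post_ov", rate = sm$case_psych_post, ward = "psychiatric",
         losm = sm$psych_los_median, loss = sm$psych_los_sigma),
    list(tag = 3L, rate_col = "pre_ov", rate = sm$case_nonpsych_pre, ward = "non_psychiatric",
         losm = sm$nonpsych_los_median, loss = sm$nonpsych_los_sigma),
    list(tag = 4L, rate_col = "post_ov", rate = sm$case_nonpsych_post, ward = "non_psychiatric",
         losm = sm$nonpsych_los_median, loss = sm$nonpsych_los_sigma)
  )
  out <- list()
  for (p in procs) {
    g <- yg[get(p$rate_col) > 0]
    if (nrow(g) == 0L) next
    g <- g[, .(id, y, ys, ye, res_start, ev_end, onset, dur, ov = get(p$rate_col))]
    g[, cnt := pmin(qpois(hash_unif(seed, id, 50000 + p$tag * 100 + y),
                          p$rate * ov / 365), 3L)]
    g <- g[cnt > 0][rep(seq_len(.N), cnt)][, k := data.table::rowid(id, y)]
    if (nrow(g) == 0L) next
    # admission uniform over the phase-overlap part of the year
    if (p$rate_col == "avail") { g[, `:=`(lo = pmax(ys, res_start), hi = pmin(ye, ev_end))]
    } else if (p$rate_col == "pre_ov") { g[, `:=`(lo = pmax(ys, res_start, onset - 365),
                                                  hi = pmin(ye, ev_end, onset))]
    } else g[, `:=`(lo = pmax(ys, res_start, onset), hi = pmin(ye, ev_end, onset + dur))]
    g[, adm := lo + floor(hash_unif(seed, id, 51000 + p$tag * 100 + y * 4 + k) *
                            pmax(hi - lo, 1))]
    g[, los := pmax(1, round(qlnorm(hash_unif(seed, id, 52000 + p$tag * 100 + y * 4 + k),
                                    log(p$losm), p$loss)))]
    g[, dis := pmin(adm + los, ev_end)]
    out[[length(out) + 1L]] <- g[adm >= lo & adm < ev_end & dis > adm,
                                 .(id, adm, dis, ward = p$ward)]
  }
  if (!length(out))
    return(data.table::data.table(id = integer(), adm = numeric(), dis = numeric(),
                                  ward = character()))
  data.table::rbindlist(out)
}

# work-loss spells: sick leave (background + case pre/post processes) and
# person-level disability pension; only persons aged 20-64 at spell start
sim_workloss <- function(yg, cfg, seed) {
  wm <- cfg$workloss_model
  procs <- list(
    list(tag = 0L, rate_col = "avail", rate = wm$sick_base_rate, med = wm$sick_base_median),
    list(tag = 1L, rate_col = "pre_ov", rate = wm$sick_case_pre_rate, med = wm$sick_case_pre_median),
    list(tag = 2L, rate_col = "post_ov", rate = wm$sick_case_post_rate, med = wm$sick_case_post_median)
  )
  out <- list()
  for (p in procs) {
    g <- yg[get(p$rate_col) > 0]
    if (nrow(g) == 0L) next
    g <- g[, .(id, y, ys, ye, res_start, ev_end, onset, dur, birth, ov = get(p$rate_col))]
    g[, cnt := pmin(qpois(hash_unif(seed, id, 60000 + p$tag * 100 + y),
                          p$rate * ov / 365), 3L)]
    g <- g[cnt > 0][rep(seq_len(.N), cnt)][, k := data.table::rowid(id, y)]
    if (nrow(g) == 0L) next
    if (p$rate_col == "avail") { g[, `:=`(lo = pmax(ys, res_start), hi = pmin(ye, ev_end))]
    } else if (p$rate_col == "pre_ov") { g[, `:=`(lo = pmax(ys, res_start, onset - 365),
                                                  hi = pmin(ye, ev_end, onset))]
    } else g[, `:=`(lo = pmax(ys, res_start, onset), hi = pmin(ye, ev_end, onset + dur))]
    g[, s := lo + floor(hash_unif(seed, id, 61000 + p$tag * 100 + y * 4 + k) *
                          pmax(hi - lo, 1))]
    g[, dd := pmax(1, round(qlnorm(hash_unif(seed, id, 62000 + p$tag * 100 + y * 4 + k),
                                   log(p$med), wm$sick_sigma)))]
    g[, e := pmin(s + dd, ev_end)]
    g[, extent := ifelse(hash_unif(seed, id, 63000 + p$tag * 100 + y * 4 + k) <
                           wm$p_extent_full, 1, 0.5)]
    # ages 20-64 at spell start
    g[, age := (s - birth) / 365.25]
    out[[length(out) + 1L]] <- g[e > s & age >= 20 & age < 65,
                                 .(id, s, e, kind = "sick_leave", extent)]
  }
  # disability pension: long person-level spells with stable extent
  pp <- unique(yg[, .(id, res_start, res_end, ev_end, onset, dur, is_case, birth)])
  u <- hash_unif(cfg$seed, pp$id, 23)
  pdp <- ifelse(pp$is_case, wm$dp_p_case, wm$dp_p_control)
  dp <- pp[u < pdp]
  if (nrow(dp)) {
    dp[, lo := pmax(res_start, birth + 20 * 365.25)]
    dp[, hi := pmin(ev_end, birth + 65 * 365.25)]
    dp <- dp[hi > lo]
    dp[, s := round(lo + hash_unif(cfg$seed, id, 24) * (hi - lo))]
    dp[, e := round(hi)]
    dp[, extent := ifelse(hash_unif(cfg$seed, id, 25) < wm$dp_p_extent_full, 1, 0.5)]
    dp <- dp[e > s, .(id, s, e, kind = "disability_pension", extent)]
    out[[length(out) + 1L]] <- dp
  }
  if (!length(out))
    return(data.table::data.table(id = integer(), s = numeric(), e = numeric(),
                                  kind = character(), extent = numeric()))
  data.table::rbindlist(out)
}

# outpatient visits: monthly Poisson counts at phase-dependent physician-visit
# rates plus a nurse (non-physician) stream
sim_visits <- function(P, cfg, seed, w0, w1) {
  ms <- seq(w0, w1, by = "month")
  msn <- as.numeric(ms)
  nm <- length(ms) - 1L
  gv <- data.table::CJ(id = P$id, j = seq_len(nm) - 1L)
  gv <- merge(gv, P[, .(id, res_start, ev_end, onset, dur, is_case)], by = "id")
  gv[, `:=`(mstart = msn[j + 1L], mend = msn[j + 2L])]
  gv[, mid := (mstart + mend) / 2]
  gv <- gv[mid >= res_start & mid < ev_end]
  vr <- cfg$visit_rates
  gv[, phase := data.table::fcase(
    is_case & mid >= onset & mid < onset + dur, "post",
    is_case & mid >= onset - 365 & mid < onset, "pre",
    default = "base")]
  gv[, lam := data.table::fcase(phase == "post", vr$case_post,
                                phase == "pre", vr$case_pre,
                                default = vr$base) / 12]
  gv[, cnt := pmin(qpois(hash_unif(seed, id, 10000 + j), lam), 6L)]
  vv <- gv[cnt > 0][rep(seq_len(.N), cnt)][, k := data.table::rowid(id, j)]
  mixb <- cfg$visit_level_mix$base; mixc <- cfg$visit_level_mix$case
  lv3 <- c("primary", "psychiatric", "other")
  if (nrow(vv)) {
    vv[, date := mstart + floor(hash_unif(seed, id, 20000 + j * 8 + k) * (mend - mstart))]
    ul <- hash_unif(seed, vv$id, 30000 + vv$j * 8 + vv$k)
    vv[, lvl := ifelse(phase == "base", pick(ul, mixb, lv3), pick(ul, mixc, lv3))]
    vv[, care_level := data.table::fcase(
      lvl == "psychiatric", "psychiatric_outpatient",
      lvl == "primary", "primary", default = "other")]
    phys <- vv[, .(id, date, care_level, physician = TRUE)]
  } else phys <- data.table::data.table(id = integer(), date = numeric(),
                                        care_level = character(), physician = logical())
  gv[, ncnt := pmin(qpois(hash_unif(seed, id, 40000 + j), cfg$nurse_visit_rate_per_month), 2L)]
  nv <- gv[ncnt > 0][rep(seq_len(.N), ncnt)][, k := data.table::rowid(id, j)]
  if (nrow(nv)) {
    nv[, date := mstart + floor(hash_unif(seed, id, 41000 + j * 4 + k) * (mend - mstart))]
    nurse <- nv[, .(id, date, care_level = "primary", physician = FALSE)]
  } else nurse <- phys[0]
  out <- data.table::rbindlist(list(phys, nurse))
  out <- merge(out, P[, .(id, res_start, ev_end)], by = "id")
  out <- out[date >= res_start & date < ev_end]
  out[, c("res_start", "ev_end") := NULL]
  out
}

empty_tables <- function() {
  schemas <- registry_schemas()
  tabs <- lapply(schemas, function(sch) {
    cols <- lapply(sch$cols, function(ty) switch(ty,
      character = character(), date = as.Date(character()),
      integer = integer(), numeric = numeric(), logical = logical()))
    data.table::as.data.table(cols)
  })
  class(tabs) <- c("registry_tables", "list")
  tabs
}

empty_truth <- function() {
  data.table::data.table(person_id = character(), onset_date = as.Date(character()),
                         true_end = as.Date(character()), true_duration_days = numeric(),
                         hazard_mult = numeric(), care_level_at_onset = character(),
                         ad_start = as.Date(character()), ad_stop = as.Date(character()))
}

#' Write the ground-truth table to CSV
#'
#' One row per simulated MDD onset; an empty truth writes the header only.
#'
#' @param truth the `truth` element of [generate_registry()]'s result.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
truth_report <- function(truth, path) {
  data.table::fwrite(truth, path, dateTimeAs = "ISO", logical01 = FALSE,
                     na = "", quote = FALSE, eol = "\n")
  invisible(path)
}

#' Simulate a matched case-control survival cohort
#'
#' A direct draw from the generator's mortality model for hazard-ratio
#' recovery studies: exponential baseline mortality in controls, the case
#' hazard multiplied by `exp(log_hr)` from index onward, index dates uniform
#' over a follow-up window with administrative end censoring, and exponential
#' emigration. With the defaults (7-year window, emigration 0.15/year) the
#' mean follow-up is about 2.5 years.
#'
#' @param n_pairs number of case-control pairs.
#' @param log_hr true case log hazard ratio (default `log(2.2)`).
#' @param baseline_rate_per_1000py control mortality rate (default 5.4).
#' @param window_years administrative follow-up window (default 7).
#' @param emigration_rate_per_year censoring hazard (default 0.15).
#' @param seed integer seed.
#' @return `data.table` with `pair_id`, `group` (`"mdd"`/`"control"`), `time`
#'   (days, zero clamped to 0.5), `event` (death indicator).
#' @export
simulate_matched_survival <- function(n_pairs, log_hr = log(2.2),
                                      baseline_rate_per_1000py = 5.4,
                                      window_years = 7,
                                      emigration_rate_per_year = 0.15,
                                      seed = 1L) {
  stopifnot(n_pairs >= 1)
  ids <- seq_len(n_pairs)
  lam <- baseline_rate_per_1000py / 1000 / 365.25
  admin <- hash_unif(seed, ids, 1) * window_years * 365.25
  emig_ca <- qexp_u(hash_unif(seed, ids, 2), emigration_rate_per_year / 365.25)
  emig_co <- qexp_u(hash_unif(seed, ids, 3), emigration_rate_per_year / 365.25)
  death_ca <- qexp_u(hash_unif(seed, ids, 4), lam * exp(log_hr))
  death_co <- qexp_u(hash_unif(seed, ids, 5), lam)
  mk <- function(death, emig, grp) {
    cens <- pmin(admin, emig)
    data.table::data.table(pair_id = ids, group = grp,
                           time = pmax(pmin(death, cens), 0.5),
                           event = death <= cens)
  }
  out <- data.table::rbindlist(list(mk(death_ca, emig_ca, "mdd"),
                                    mk(death_co, emig_co, "control")))
  data.table::setorderv(out, c("pair_id", "group"))
  out[]
}
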