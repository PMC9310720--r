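# Independent brute-force oracle for the episode-stitching algorithm: a
# day-grid flood fill computed by fixpoint iteration, stepping the published
# rules without sharing code with build_episodes.

oracle_episodes <- function(events, G, cap = 100L, data_end,
                            tablets_per_day = 1) {
  ev <- as.data.table(events)[date <= data_end]
  # collapse to event days
  dd <- ev[, .(has_dx = any(event_class == "diagnosis"),
               has_disp = any(event_class == "dispensation"),
               tabs = sum(tablets[event_class == "dispensation"], na.rm = TRUE)),
           by = date][order(date)]
  days <- as.numeric(dd$date)
  n <- length(days)
  used <- rep(FALSE, n)
  eps <- list()
  repeat {
    starts <- which(!used & dd$has_dx)
    if (!length(starts)) break
    s <- starts[1]
    inset <- rep(FALSE, n)
    inset[s] <- TRUE
    # flood fill: add any later event day within G of some in-set day before it
    repeat {
      grew <- FALSE
      for (j in seq_len(n)) {
        if (!inset[j] && days[j] > days[s]) {
          if (any(inset & days < days[j] & (days[j] - days) <= G)) {
            inset[j] <- TRUE
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    memb <- which(inset)
    last <- max(memb)
    used[days <= days[last]] <- TRUE
    if ((as.numeric(data_end) - days[last]) <= G) {
      end <- days[last]; closure <- "open_at_data_end"
    } else if (dd$has_disp[last]) {
      end <- days[last] + min(floor(dd$tabs[last] / tablets_per_day), cap)
      closure <- "extension_after_gap"
    } else {
      end <- days[last]; closure <- "gap"
    }
    eps[[length(eps) + 1L]] <- data.table(
      start_date = dd$date[s],
      end_date = as.Date(end, origin = "1970-01-01"),
      closure = closure, n_events = length(memb))
  }
  out <- rbindlist(eps)
  out[, ordinal := seq_len(.N)]
  setcolorder(out, c("ordinal", "start_date", "end_date", "closure", "n_events"))
  out[]
}

# random depressive-event stream whose first event is a diagnosis
rand_stream <- function(n_events, horizon = 2500, base = D("2012-01-01")) {
  days <- sort(sample.int(horizon, n_events, replace = TRUE)) - 1L
  days[1] <- 0L
  classes <- sample(c("diagnosis", "dispensation", "procedure"), n_events,
                    replace = TRUE, prob = c(0.4, 0.4, 0.2))
  classes[which(days == 0L)[1]] <- "diagnosis"
  tabs <- ifelse(classes == "dispensation",
                 sample(c(10L, 30L, 100L, 250L), n_events, replace = TRUE),
                 NA_integer_)
  ev_stream(days, classes, tabs, base = base)
}
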