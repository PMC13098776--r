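#' Define an alerting policy for deployment emulation
#'
#' @param interval prediction interval in hours (risk is recomputed every
#'   `interval` hours over the whole stay); typical values 1, 2, 12.
#' @param threshold alert threshold on the predicted probability; an alert
#'   fires when probability `>= threshold` (set `strict = TRUE` for a
#'   strict `>`).
#' @param refractory hours after a fired alert during which no further
#'   alert may fire (open interval: the first grid point at or after
#'   `alert + refractory` is eligible again); re-anchors on every fired
#'   alert.
#' @param censor hours after each deterioration event during which alerts
#'   are suppressed (`[event, event + censor)`); post-event alerts carry no
#'   preparatory value.
#' @param window detection look-back in hours: an event counts as detected
#'   when an alert fired in `[event - window, event)`.
#' @param strict use strict `>` threshold comparison.
#' @param lead `"earliest"` (default) or `"latest"`: which qualifying alert
#'   defines an event's lead time.
#' @return an object of class `alert_policy`.
#' @export
alert_policy <- function(interval = 1, threshold = 0.5, refractory = 0,
                         censor = 24, window = 24, strict = FALSE,
                         lead = c("earliest", "latest")) {
  stopifnot(interval > 0, threshold >= 0, threshold <= 1,
            refractory >= 0, censor >= 0, window >= 0)
  structure(list(interval = interval, threshold = threshold,
                 refractory = refractory, censor = censor, window = window,
                 strict = strict, lead = match.arg(lead)),
            class = "alert_policy")
}

#' @export
print.alert_policy <- function(x, ...) {
  cat(sprintf(
    "Alert policy: every %g h, threshold %s %.3g, refractory %g h, post-event censor %g h, detection window %g h\n",
    x$interval, if (x$strict) ">" else ">=", x$threshold, x$refractory,
    x$censor, x$window))
  invisible(x)
}

#' Prediction grid over a stay
#'
#' Grid times are `start, start + interval, ...` up to and including the
#' stay end when it falls on the grid.
#'
#' @param start,end stay bounds (numeric hours or POSIXct).
#' @param interval prediction interval in hours.
#' @return numeric vector of grid times in hours.
#' @export
prediction_grid <- function(start, end, interval) {
  stopifnot(interval > 0)
  s <- .as_hours(start); e <- .as_hours(end)
  if (e < s) .stopf("stay end precedes start")
  seq(s, e, by = interval)
}

# Censor mask for one admission's grid: TRUE where an event's censor
# window [e, e + censor) covers the grid time.
.censored_at <- function(times, event_times, censor) {
  if (!length(event_times) || censor <= 0) return(rep(FALSE, length(times)))
  out <- rep(FALSE, length(times))
  for (e in event_times) out <- out | (times >= e & times < e + censor)
  out
}

#' Simulate deployment alerts for risk series
#'
#' Chronological scan per admission: an alert fires at grid time `t` iff
#' the probability meets the threshold, `t` is at least `refractory` hours
#' after the previous fired alert (the refractory re-anchors on each fired
#' alert), and `t` is not inside any event's post-event censoring window
#' `[event, event + censor)`.  Deterministic.
#'
#' @param scores long-format risk series: `admission_id`, `time`,
#'   `probability` (times numeric hours or POSIXct; must be sorted or
#'   sortable per admission; duplicated grid times are an error).
#' @param events confirmed deterioration events (`admission_id`,
#'   `event_time`); pass all events, including early-stay ones.
#' @param policy an [alert_policy()].
#' @return data frame of alerts: `admission_id`, `alert_time` (hours),
#'   `probability`.
#' @export
simulate_alerts <- function(scores, events, policy) {
  .require_cols(scores, c("admission_id", "time", "probability"), "scores")
  if (any(scores$probability < 0 | scores$probability > 1, na.rm = TRUE))
    .stopf("probabilities must lie in [0, 1]")
  tt <- .as_hours(scores$time)
  ev_t <- if (nrow(events)) .as_hours(events$event_time) else numeric(0)
  ev_split <- split(ev_t, if (nrow(events)) events$admission_id else character(0))
  adm_of <- split(seq_len(nrow(scores)), scores$admission_id)
  acc <- vector("list", length(adm_of))
  k <- 0L
  for (adm in names(adm_of)) {
    sel <- adm_of[[adm]]
    o <- sel[order(tt[sel])]
    g <- tt[o]
    if (anyDuplicated(g)) .stopf("duplicated grid times for admission %s", adm)
    p <- scores$probability[o]
    pass <- if (policy$strict) p > policy$threshold else p >= policy$threshold
    pass[is.na(pass)] <- FALSE
    pass <- pass & !.censored_at(g, ev_split[[adm]], policy$censor)
    cand <- which(pass)
    if (policy$refractory <= 0) {
      fired <- cand
    } else {
      fired <- integer(length(cand))
      nf <- 0L
      next_ok <- -Inf
      for (i in cand) {
        if (g[i] >= next_ok) {
          nf <- nf + 1L
          fired[nf] <- i
          next_ok <- g[i] + policy$refractory
        }
      }
      fired <- fired[seq_len(nf)]
    }
    if (length(fired)) {
      k <- k + 1L
      acc[[k]] <- data.frame(admission_id = rep(adm, length(fired)),
                             alert_time = g[fired], probability = p[fired],
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(admission_id = character(), alert_time = numeric(),
                      probability = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, acc[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Which events had an advance alert
#'
#' An event is detected when some alert of the same admission fired inside
#' the half-open look-back window `[event - window, event)`; an alert at
#' the event instant is not advance warning.
#'
#' @param alerts output of [simulate_alerts()].
#' @param events all confirmed deterioration events (no early-stay
#'   exclusion here, in contrast to model training).
#' @param window detection window in hours (default 24).
#' @return list with `fraction` (`NA` when there are no events), and
#'   `flags`: per-event data frame with `detected` and `lead_earliest` /
#'   `lead_latest` hours (NA when undetected).
#' @export
detection_fraction <- function(alerts, events, window = 24) {
  if (nrow(events) == 0)
    return(list(fraction = NA_real_,
                flags = data.frame(admission_id = character(),
                                   event_time = numeric(),
                                   detected = logical(),
                                   lead_earliest = numeric(),
                                   lead_latest = numeric())))
  ev_t <- .as_hours(events$event_time)
  al_split <- split(alerts$alert_time, alerts$admission_id)
  detected <- logical(nrow(events))
  lead_e <- lead_l <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    a <- al_split[[events$admission_id[i]]]
    if (is.null(a)) next
    q <- a[a >= ev_t[i] - window & a < ev_t[i]]
    if (length(q)) {
      detected[i] <- TRUE
      lead_e[i] <- ev_t[i] - min(q)
      lead_l[i] <- ev_t[i] - max(q)
    }
  }
  list(fraction = mean(detected),
       flags = data.frame(admission_id = events$admission_id,
                          event_time = ev_t, detected = detected,
                          lead_earliest = lead_e, lead_latest = lead_l,
                          stringsAsFactors = FALSE))
}

#' Burden and detection metrics of a simulated deployment
#'
#' Reports alerts per patient-day (total alerts over total stay-days; the
#' denominator is the full stay, including censored and refractory time),
#' the detected fraction of events, the median and interquartile range of
#' lead times over detected events (lead = event time minus the earliest
#' qualifying alert in the window, or latest under `policy$lead =
#' "latest"`), and the admission-level number needed to alert: admissions
#' with at least one alert per admission with both an alert and a detected
#' event.
#'
#' @inheritParams detection_fraction
#' @param admissions admission table (`admission_id`, `picu_start`,
#'   `picu_end`) defining the patient-day denominator.
#' @param policy an [alert_policy()] (supplies `window` and the lead-time
#'   convention).
#' @return an object of class `burden_report` (a list of metrics and
#'   counts).
#' @export
burden_metrics <- function(alerts, events, admissions, policy) {
  dur <- .hours_between(admissions$picu_end, admissions$picu_start)
  patient_days <- sum(dur) / 24
  if (patient_days <= 0) .stopf("zero patient-days in the admission table")
  det <- detection_fraction(alerts, events, window = policy$window)
  leads <- if (policy$lead == "earliest") det$flags$lead_earliest else
    det$flags$lead_latest
  leads <- leads[det$flags$detected]
  flagged <- unique(alerts$admission_id)
  det_adm <- unique(det$flags$admission_id[det$flags$detected])
  denom <- length(intersect(flagged, det_adm))
  structure(list(
    alerts_per_patient_day = nrow(alerts) / patient_days,
    detection_fraction = det$fraction,
    lead_median = if (length(leads)) stats::median(leads) else NA_real_,
    lead_iqr = if (length(leads))
      stats::quantile(leads, c(0.25, 0.75), names = FALSE) else
        c(NA_real_, NA_real_),
    admission_nna = if (denom > 0) length(flagged) / denom else NA_real_,
    n_alerts = nrow(alerts),
    n_events = nrow(events),
    n_detected = sum(det$flags$detected),
    n_flagged_admissions = length(flagged),
    patient_days = patient_days,
    event_flags = det$flags
  ), class = "burden_report")
}

#' @export
print.burden_report <- function(x, digits = 3, ...) {
  cat("Deployment emulation burden report\n")
  cat(sprintf("  alerts/patient-day: %.*g  (%d alerts over %.1f patient-days)\n",
              digits, x$alerts_per_patient_day, x$n_alerts, x$patient_days))
  cat(sprintf("  detection: %s of %d events\n",
              ifelse(is.na(x$detection_fraction), "NA",
                     sprintf("%.1f%%", 100 * x$detection_fraction)),
              x$n_events))
  if (!is.na(x$lead_median))
    cat(sprintf("  lead time: median %.2f h (IQR %.2f-%.2f)\n",
                x$lead_median, x$lead_iqr[1], x$lead_iqr[2]))
  cat(sprintf("  admission-level NNA: %s\n",
              ifelse(is.na(x$admission_nna), "undefined",
                     sprintf("%.*g", digits, x$admission_nna))))
  invisible(x)
}

#' Sweep the alert threshold and trace the detection-burden tradeoff
#'
#' Runs [simulate_alerts()] + [burden_metrics()] at each threshold.
#' Alerts per patient-day are verified non-increasing in the threshold (a
#' structural property of the simulator); a detection fraction that is not
#' non-increasing — possible only through rare refractory-shift artifacts —
#' triggers a warning.
#'
#' @inheritParams burden_metrics
#' @param scores long-format risk series (see [simulate_alerts()]).
#' @param thresholds ascending thresholds to evaluate.
#' @return an object of class `sweep_curve`: data frame with one row per
#'   threshold (`threshold`, `alerts_per_patient_day`,
#'   `detection_fraction`, `lead_median`, `lead_iqr_lo`, `lead_iqr_hi`,
#'   `nna`, `n_alerts`, `n_detected`), with the full reports in attribute
#'   `"reports"`.
#' @export
sweep_thresholds <- function(scores, events, admissions, policy, thresholds) {
  thresholds <- sort(thresholds)
  reports <- vector("list", length(thresholds))
  rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    pol <- policy
    pol$threshold <- thresholds[i]
    al <- simulate_alerts(scores, events, pol)
    rep <- burden_metrics(al, events, admissions, pol)
    reports[[i]] <- rep
    rows[[i]] <- data.frame(
      threshold = thresholds[i],
      alerts_per_patient_day = rep$alerts_per_patient_day,
      detection_fraction = rep$detection_fraction,
      lead_median = rep$lead_median,
      lead_iqr_lo = rep$lead_iqr[1], lead_iqr_hi = rep$lead_iqr[2],
      nna = rep$admission_nna, n_alerts = rep$n_alerts,
      n_detected = rep$n_detected)
  }
  curve <- do.call(rbind, rows)
  if (any(diff(curve$alerts_per_patient_day) > 1e-12))
    .stopf("alert burden increased with threshold; simulator invariant violated")
  if (any(diff(curve$detection_fraction) > 1e-12, na.rm = TRUE))
    .warnf("detection fraction increased with threshold (refractory-shift artifact)")
  attr(curve, "reports") <- reports
  class(curve) <- c("sweep_curve", class(curve))
  curve
}

#' Pick the threshold meeting a detection target at minimal burden
#'
#' Returns the largest threshold whose detection fraction meets the target
#' (larger thresholds alert less, so this is the minimal-burden choice).
#'
#' @param curve a [sweep_thresholds()] result.
#' @param target required detection fraction in `[0, 1]`.
#' @return list with `threshold` and the corresponding `report`.
#' @export
threshold_for_detection <- function(curve, target) {
  if (nrow(curve) == 0) .stopf("empty sweep curve")
  ok <- which(!is.na(curve$detection_fraction) &
                curve$detection_fraction >= target)
  if (!length(ok))
    .stopf("detection target %.2f unreachable (max achievable %.3f)",
           target, max(curve$detection_fraction, na.rm = TRUE))
  i <- ok[which.max(curve$threshold[ok])]
  list(threshold = curve$threshold[i],
       report = attr(curve, "reports")[[i]])
}

#' Burden metrics for a binary alerting tool
#'
#' Runs an existing rule-based tool's binary indicator stream (1 = the tool
#' alerted in the past interval) through the identical simulation path:
#' the indicator is treated as a probability in `{0, 1}` with threshold
#' 0.5, subject to the same refractory period and post-event censoring.
#'
#' @param indicator long-format stream (`admission_id`, `time`, `value`
#'   with values in `{0, 1}`), typically on an hourly grid.
#' @inheritParams burden_metrics
#' @return a `burden_report` (see [burden_metrics()]).
#' @export
binary_tool_burden <- function(indicator, events, admissions, policy) {
  .require_cols(indicator, c("admission_id", "time", "value"), "indicator")
  if (!all(indicator$value %in% c(0, 1)))
    .stopf("indicator stream must be binary (0/1)")
  pol <- policy
  pol$threshold <- 0.5
  pol$strict <- FALSE
  scores <- data.frame(admission_id = indicator$admission_id,
                       time = indicator$time,
                       probability = as.numeric(indicator$value))
  alerts <- simulate_alerts(scores, events, pol)
  burden_metrics(alerts, events, admissions, pol)
}
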