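#' Merge PICU stays separated by short absences
#'
#' Stays belonging to the same hospital encounter whose gap out of the PICU
#' is shorter than `gap_hours` are combined into a single continuous
#' admission spanning the earliest start to the latest end.  Gaps of
#' `gap_hours` or more leave the stays as separate admissions.  The merged
#' record keeps the identifiers and demographics of the earliest stay.
#'
#' @param stays data frame with columns `patient_id`, `admission_id`,
#'   `encounter_id`, `encounter_start`, `picu_start`, `picu_end` plus any
#'   demographic columns (carried through from the first stay of a merge).
#' @param gap_hours maximum PICU-absence gap (hours) that still merges; the
#'   clinical convention is 24 h.
#' @return data frame with the same columns, one row per merged admission.
#'   Idempotent: merging an already-merged table is a no-op.
#' @export
merge_admissions <- function(stays, gap_hours = 24) {
  .require_cols(stays, c("patient_id", "admission_id", "encounter_id",
                         "picu_start", "picu_end"), "stays")
  if (nrow(stays) == 0) return(stays)
  ord <- order(stays$encounter_id, .as_hours(stays$picu_start))
  stays <- stays[ord, , drop = FALSE]
  out <- vector("list", nrow(stays))
  n_out <- 0L
  cur <- NULL
  for (i in seq_len(nrow(stays))) {
    row <- stays[i, , drop = FALSE]
    if (.as_hours(row$picu_end) <= .as_hours(row$picu_start))
      .stopf("stay %s has picu_end <= picu_start", row$admission_id)
    if (!is.null(cur) && identical(cur$encounter_id, row$encounter_id)) {
      gap <- .hours_between(row$picu_start, cur$picu_end)
      if (gap < 0)
        .stopf("overlapping stays within encounter %s (stay %s starts before prior stay ends)",
               row$encounter_id, row$admission_id)
      if (gap < gap_hours) {
        cur$picu_end <- max(cur$picu_end, row$picu_end)
        next
      }
    }
    if (!is.null(cur)) { n_out <- n_out + 1L; out[[n_out]] <- cur }
    cur <- row
  }
  if (!is.null(cur)) { n_out <- n_out + 1L; out[[n_out]] <- cur }
  res <- do.call(rbind, out[seq_len(n_out)])
  rownames(res) <- NULL
  res
}

#' Apply cohort inclusion criteria
#'
#' Retains admissions with a PICU stay of at least `min_stay_hours` and an
#' age at admission inside `[0, max_age_years)`.  The upper age bound is
#' exclusive at 25 years so that 24-year-olds remain eligible.  Exclusion
#' counts in the style of a cohort flowchart are attached as the
#' `"flow"` attribute (input, excluded by duration, excluded by age among
#' the remainder, retained).
#'
#' @param admissions merged admissions (see [merge_admissions()]) with an
#'   `age_years` column.
#' @param min_stay_hours minimum stay duration in hours (default 24).
#' @param max_age_years exclusive upper age bound in years (default 25).
#' @return the retained admissions, with attribute `flow` (a named list of
#'   counts).
#' @export
apply_inclusion <- function(admissions, min_stay_hours = 24, max_age_years = 25) {
  .require_cols(admissions, c("picu_start", "picu_end", "age_years"),
                "admissions")
  dur <- .hours_between(admissions$picu_end, admissions$picu_start)
  short <- dur < min_stay_hours
  bad_age <- !short & (admissions$age_years < 0 |
                         admissions$age_years >= max_age_years)
  keep <- !short & !bad_age
  out <- admissions[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flow") <- list(
    input = nrow(admissions),
    excluded_duration = sum(short),
    excluded_age = sum(bad_age),
    retained = sum(keep)
  )
  out
}

#' Confirm unplanned endotracheal intubations
#'
#' An intubation counts as an unplanned endotracheal intubation (UEI) when
#' it persists for at least `persist_hours` (48 h by default), a proxy that
#' excludes elective and procedural airway management.  Intubations still
#' ongoing at PICU discharge (missing `extubation_time`) are confirmed and
#' flagged `ongoing_at_end` for sensitivity analysis.  If a logical
#' `planned` column is present, planned procedures are rejected before the
#' persistence rule is applied.
#'
#' @param intubations data frame of intubation events with `admission_id`,
#'   `event_time`, and `extubation_time` (NA when still intubated at the
#'   end of the stay); optionally `planned`.
#' @param persist_hours persistence threshold in hours (default 48).
#' @return the input with logical columns `confirmed` and `ongoing_at_end`.
#' @export
classify_uei <- function(intubations, persist_hours = 48) {
  .require_cols(intubations, c("admission_id", "event_time",
                               "extubation_time"), "intubations")
  t0 <- .as_hours(intubations$event_time)
  t1 <- .as_hours(intubations$extubation_time)
  if (any(!is.na(t1) & t1 < t0))
    .stopf("extubation_time precedes event_time for admission %s",
           intubations$admission_id[which(!is.na(t1) & t1 < t0)[1]])
  ongoing <- is.na(t1)
  confirmed <- ifelse(ongoing, TRUE, (t1 - t0) >= persist_hours)
  if (!is.null(intubations$planned))
    confirmed <- confirmed & !(intubations$planned %in% TRUE)
  intubations$confirmed <- confirmed
  # flag the presumed confirmations where <48 h had elapsed before discharge
  intubations$ongoing_at_end <- ongoing
  intubations
}

#' Deduplicate deterioration events within an admission
#'
#' Events that occur within `lockout_hours` of a prior event in the same
#' admission are treated as part of the same deterioration trajectory and
#' dropped.  The default anchoring convention (`"kept"`) is a greedy
#' chronological pass: an event is kept iff it falls at least
#' `lockout_hours` after the last *kept* event, so a suppressed event never
#' extends the lockout.  With `anchor = "raw"` the lockout instead
#' re-anchors on every candidate event, kept or not.
#'
#' @param events data frame with `admission_id`, `event_type`, `event_time`
#'   (confirmed deterioration events).
#' @param lockout_hours minimum within-admission gap in hours (default 8);
#'   a gap of exactly `lockout_hours` is retained.
#' @param anchor `"kept"` (default) or `"raw"`.
#' @return the subset of `events` that survives, in chronological order per
#'   admission.
#' @export
deduplicate_events <- function(events, lockout_hours = 8,
                               anchor = c("kept", "raw")) {
  anchor <- match.arg(anchor)
  .require_cols(events, c("admission_id", "event_time"), "events")
  if (nrow(events) == 0) return(events)
  ord <- order(events$admission_id, .as_hours(events$event_time))
  events <- events[ord, , drop = FALSE]
  keep <- logical(nrow(events))
  last_adm <- NULL
  last_anchor <- -Inf
  for (i in seq_len(nrow(events))) {
    adm <- events$admission_id[i]
    t <- .as_hours(events$event_time[i])
    if (!identical(adm, last_adm)) {
      last_adm <- adm
      last_anchor <- -Inf
    }
    ok <- (t - last_anchor) >= lockout_hours
    keep[i] <- ok
    if (ok || anchor == "raw") last_anchor <- t
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confirm the composite critical deterioration events of a cohort
#'
#' Convenience wrapper over the event rules: CPR, ECMO and dilute
#' epinephrine bolus events pass through directly; intubations are
#' confirmed as UEI by the 48-hour persistence rule
#' ([classify_uei()]); the confirmed set is then deduplicated with the
#' 8-hour lockout ([deduplicate_events()]) and restricted to admissions
#' present in `admissions`.
#'
#' @param events raw event table (`admission_id`, `event_type`,
#'   `event_time`, `extubation_time`); `event_type` of intubations may be
#'   `"INTUBATION"` or `"UEI"`.
#' @param admissions cohort admissions; events are clipped to this set and
#'   checked to lie within the stay.
#' @inheritParams deduplicate_events
#' @param persist_hours UEI persistence threshold (default 48).
#' @return confirmed, deduplicated events with `event_type` of intubations
#'   rewritten to `"UEI"`; carries `ongoing_at_end` where applicable.
#' @export
confirm_cde <- function(events, admissions, lockout_hours = 8,
                        persist_hours = 48, anchor = "kept") {
  .require_cols(events, c("admission_id", "event_type", "event_time"),
                "events")
  events <- events[events$admission_id %in% admissions$admission_id, ,
                   drop = FALSE]
  if (nrow(events) == 0) return(events)
  start <- .as_hours(admissions$picu_start)[match(events$admission_id,
                                                  admissions$admission_id)]
  end <- .as_hours(admissions$picu_end)[match(events$admission_id,
                                              admissions$admission_id)]
  tt <- .as_hours(events$event_time)
  if (any(tt < start | tt > end))
    .stopf("event outside its admission window (admission %s)",
           events$admission_id[which(tt < start | tt > end)[1]])
  is_intub <- events$event_type %in% c("INTUBATION", "UEI")
  events$ongoing_at_end <- FALSE
  if (any(is_intub)) {
    intub <- events[is_intub, , drop = FALSE]
    if (is.null(intub$extubation_time)) intub$extubation_time <- NA
    cls <- classify_uei(intub, persist_hours = persist_hours)
    cls <- cls[cls$confirmed, , drop = FALSE]
    cls$event_type <- rep("UEI", nrow(cls))
    cls$confirmed <- NULL
    other <- events[!is_intub, , drop = FALSE]
    cls <- cls[, names(other), drop = FALSE]
    events <- rbind(other, cls)
  }
  deduplicate_events(events, lockout_hours = lockout_hours, anchor = anchor)
}

#' Temporally split a cohort at a boundary date
#'
#' Admissions whose PICU stay starts before `boundary` form the development
#' set.  Admissions starting at or after `boundary` enter the validation
#' set only when their *hospital encounter* also started at or after the
#' boundary; admissions of straddling encounters are excluded from both
#' sets (they would otherwise leak development-period context into
#' validation).
#'
#' @param admissions cohort admissions with `encounter_start` and
#'   `picu_start`.
#' @param boundary a timestamp (or value coercible by `as.POSIXct`).
#' @return an object of class `cohort_split`: a list with character vectors
#'   `development`, `validation`, `excluded_straddlers` of admission ids
#'   and the `boundary`.
#' @export
temporal_split <- function(admissions, boundary) {
  .require_cols(admissions, c("admission_id", "encounter_start",
                              "picu_start"), "admissions")
  if (is.character(boundary)) boundary <- .parse_time(boundary)
  b <- .as_hours(boundary)
  ps <- .as_hours(admissions$picu_start)
  es <- .as_hours(admissions$encounter_start)
  dev <- ps < b
  val <- ps >= b & es >= b
  straddle <- ps >= b & es < b
  structure(list(
    development = admissions$admission_id[dev],
    validation = admissions$admission_id[val],
    excluded_straddlers = admissions$admission_id[straddle],
    boundary = boundary
  ), class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("Temporal cohort split at", format(x$boundary), "\n")
  cat("  development:", length(x$development), "admissions\n")
  cat("  validation: ", length(x$validation), "admissions\n")
  cat("  excluded straddling encounters:", length(x$excluded_straddlers), "\n")
  invisible(x)
}

#' Build horizon-labelled training samples
#'
#' Each confirmed deterioration event contributes one positive snapshot per
#' prediction horizon at `event_time - horizon` (dropped when that time
#' precedes the PICU start).  Events inside the first
#' `early_exclusion_hours` of the stay are not used as training targets, so
#' an admission whose only event is early contributes nothing.  Each
#' admission without any confirmed event contributes a single control
#' snapshot drawn uniformly (1-minute resolution, closed interval) from
#' `[start + early_exclusion_hours, end - late_exclusion_hours]`, shared
#' across horizons.  Control draws are reproducible per admission: each
#' admission's stream is seeded from `(seed, admission_id)`.
#'
#' @param admissions cohort admissions (post inclusion filtering).
#' @param events confirmed, deduplicated events (see [confirm_cde()]).
#' @param horizons prediction horizons in hours (default `c(1,2,4,6,8,12)`).
#' @param seed integer seed for control-time sampling.
#' @param early_exclusion_hours leading stay window never sampled and whose
#'   events are dropped from training (default 16).
#' @param late_exclusion_hours trailing stay window never sampled for
#'   controls (default 6).
#' @return data frame with `admission_id`, `snapshot_time`, `horizon`
#'   (hours; `NA` for controls) and binary `label`.
#' @export
build_training_samples <- function(admissions, events,
                                   horizons = c(1, 2, 4, 6, 8, 12),
                                   seed = 1L,
                                   early_exclusion_hours = 16,
                                   late_exclusion_hours = 6) {
  .require_cols(admissions, c("admission_id", "picu_start", "picu_end"),
                "admissions")
  start <- .as_hours(admissions$picu_start)
  end <- .as_hours(admissions$picu_end)
  posix <- inherits(admissions$picu_start, "POSIXct")
  to_time <- function(h) if (posix) as.POSIXct(h * 3600, tz = "UTC",
                                               origin = "1970-01-01") else h
  rows <- list()
  ev_adm <- unique(events$admission_id)
  for (i in seq_len(nrow(admissions))) {
    adm <- admissions$admission_id[i]
    if (adm %in% ev_adm) {
      ev <- events[events$admission_id == adm, , drop = FALSE]
      tt <- .as_hours(ev$event_time)
      tt <- tt[tt - start[i] >= early_exclusion_hours]
      for (e in tt) {
        snap <- e - horizons
        ok <- snap >= start[i]
        if (any(ok))
          rows[[length(rows) + 1L]] <- data.frame(
            admission_id = adm, snapshot_time = snap[ok],
            horizon = horizons[ok], label = 1L,
            stringsAsFactors = FALSE)
      }
    } else {
      lo <- start[i] + early_exclusion_hours
      hi <- end[i] - late_exclusion_hours
      if (hi < lo) {
        .warnf("admission %s has no eligible control window; skipped", adm)
        next
      }
      n_min <- floor((hi - lo) * 60)
      t_ctl <- .with_seed(.derive_seed(seed, adm, "control"),
                          lo + sample.int(n_min + 1L, 1L) / 60 - 1 / 60)
      rows[[length(rows) + 1L]] <- data.frame(
        admission_id = adm, snapshot_time = t_ctl,
        horizon = NA_real_, label = 0L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(admission_id = character(), snapshot_time = numeric(),
                      horizon = numeric(), label = integer()))
  out <- do.call(rbind, rows)
  out$snapshot_time <- to_time(out$snapshot_time)
  rownames(out) <- NULL
  out
}
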