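#' Configure the synthetic EHR timeline generator
#'
#' The generator emulates the structure of a PICU cohort: admissions with
#' log-normal stay lengths, a small fraction experiencing a critical
#' deterioration event, sparse irregular vital/lab streams with AR(1)
#' autocorrelation, medication administrations as Poisson streams, and a
#' configurable pre-event physiologic deterioration signature — a linear
#' drift of standardized magnitude `effect` beginning `lead_hours` before
#' the event (medication rates are scaled by `1 + 0.25 * effect` in the
#' same window, so `effect = 0` yields a fully null signature).
#'
#' @param n_patients number of patients.
#' @param readmission_prob probability a patient has a second admission.
#' @param split_stay_prob probability an admission is emitted as two raw
#'   stays separated by a < 24 h gap (exercises [merge_admissions()]).
#' @param short_stay_prob probability of emitting a sub-24-h stay
#'   (exercises [apply_inclusion()]; default 0).
#' @param stay_meanlog,stay_sdlog log-normal stay-length parameters in
#'   hours (defaults give a median 96-h stay, mean roughly eight
#'   patient-days).
#' @param min_stay_hours lower truncation of stay length (default 24).
#' @param event_prob probability an admission experiences a deterioration
#'   event (default 0.05; realistic range 0.04-0.06).
#' @param event_mix named event-type proportions for
#'   `CPR`/`ECMO`/`EPI_BOLUS`/`UEI` (defaults mirror a development-cohort
#'   composition of 14/1/34/51%).
#' @param decoy_intubation_prob probability of an additional elective
#'   intubation (< 48 h, no signature) that must be rejected by the UEI
#'   rule.
#' @param lead_hours signature lead time tau in hours (default 12).
#' @param effect standardized drift magnitude delta (0 = no signature).
#' @param med_rate_multiplier pre-event medication rate multiplier;
#'   `NULL` (default) ties it to the effect size as `1 + 0.25 * effect`.
#' @param ar AR(1) autocorrelation per hour for vitals/labs (default 0.8).
#' @param vital_gap_mean,lab_gap_mean mean exponential inter-observation
#'   gaps in hours (1 h vitals, 8 h labs).
#' @param med_base_rate baseline medication administrations per hour.
#' @param period_start,period_days admission dates are uniform over this
#'   window (supports [temporal_split()]).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 1000, readmission_prob = 0.15,
                         split_stay_prob = 0.05, short_stay_prob = 0,
                         stay_meanlog = log(96), stay_sdlog = 0.7,
                         min_stay_hours = 24, event_prob = 0.05,
                         event_mix = c(CPR = 0.14, ECMO = 0.01,
                                       EPI_BOLUS = 0.34, UEI = 0.51),
                         decoy_intubation_prob = 0.08,
                         lead_hours = 12, effect = 2,
                         med_rate_multiplier = NULL, ar = 0.8,
                         vital_gap_mean = 1, lab_gap_mean = 8,
                         med_base_rate = 0.04,
                         period_start = "2021-01-01", period_days = 730) {
  stopifnot(event_prob >= 0, event_prob <= 1, lead_hours >= 0, effect >= 0,
            abs(sum(event_mix) - 1) < 1e-8)
  if (lead_hours > min_stay_hours)
    .stopf("infeasible config: signature lead (%g h) exceeds the minimum stay (%g h)",
           lead_hours, min_stay_hours)
  if (is.null(med_rate_multiplier)) med_rate_multiplier <- 1 + 0.25 * effect
  structure(list(
    n_patients = n_patients, readmission_prob = readmission_prob,
    split_stay_prob = split_stay_prob, short_stay_prob = short_stay_prob,
    stay_meanlog = stay_meanlog, stay_sdlog = stay_sdlog,
    min_stay_hours = min_stay_hours, event_prob = event_prob,
    event_mix = event_mix, decoy_intubation_prob = decoy_intubation_prob,
    lead_hours = lead_hours, effect = effect,
    med_rate_multiplier = med_rate_multiplier, ar = ar,
    vital_gap_mean = vital_gap_mean, lab_gap_mean = lab_gap_mean,
    med_base_rate = med_base_rate,
    period_start = period_start, period_days = period_days,
    # per-variable baselines, stationary SDs and drift direction: the
    # signature raises heart/respiratory rate and lactate and depresses
    # blood pressure and oxygen saturation
    vitals = data.frame(
      variable = c("heart_rate", "resp_rate", "sbp", "spo2"),
      baseline = c(120, 30, 95, 98), sd = c(15, 8, 12, 2.5),
      drift_sign = c(1, 1, -1, -1), stringsAsFactors = FALSE),
    labs = data.frame(
      variable = c("lactate", "wbc", "creatinine"),
      baseline = c(1.2, 9, 0.5), sd = c(0.6, 3, 0.2),
      drift_sign = c(1, 1, 1), stringsAsFactors = FALSE),
    medications = c("sedative", "vasopressor")
  ), class = "synth_config")
}

# Table 1 marginal demographic frequencies.
.demo_marginals <- list(
  sex = c(F = 0.56, M = 0.44),
  race = c(White = 0.49, Black = 0.28, Other = 0.21, Unknown = 0.01,
           Conflict = 0.01),
  ethnicity = c(Hispanic = 0.13, NonHispanic = 0.86, Unknown = 0.01),
  insurance = c(Private = 0.50, Medicaid = 0.41, Other = 0.09),
  age_cat = c(neonate = 0.01, infant = 0.39, child = 0.37,
              adolescent = 0.20, adult = 0.03)
)

.sample_cat <- function(p, n = 1) sample(names(p), n, replace = TRUE, prob = p)

.sample_age <- function() {
  cat <- .sample_cat(.demo_marginals$age_cat)
  switch(cat,
         neonate = stats::runif(1, 0, 28 / 365.25),
         infant = stats::runif(1, 28 / 365.25, 2),
         child = stats::runif(1, 2, 12),
         adolescent = stats::runif(1, 12, 19),
         adult = stats::runif(1, 19, 25))
}

# AR(1) series at irregular times with stationary SD `s` and per-hour
# autocorrelation `ar`; exact discretisation over the gaps.
.ar1_irregular <- function(times, s, ar) {
  n <- length(times)
  x <- numeric(n)
  if (n == 0) return(x)
  x[1] <- stats::rnorm(1, 0, s)
  if (n > 1) for (k in 2:n) {
    a <- ar^(times[k] - times[k - 1])
    x[k] <- a * x[k - 1] + stats::rnorm(1, 0, s * sqrt(max(0, 1 - a^2)))
  }
  x
}

# Ramp drift: 0 before onset, linear to full magnitude at the event, held
# afterwards (the patient stays deranged post-event).
.drift_at <- function(times, onset, event, magnitude) {
  if (is.na(onset)) return(numeric(length(times)))
  frac <- pmin(1, pmax(0, (times - onset) / max(event - onset, 1e-9)))
  magnitude * frac
}

#' Generate a synthetic PICU cohort
#'
#' Emits raw stay, event and observation tables plus the generator's
#' ground truth.  Running the stays through [merge_admissions()] and
#' [apply_inclusion()] and the events through [confirm_cde()] reconstructs
#' the generator's intended cohort exactly.  Fully reproducible: every
#' admission's stream is seeded from `(seed, admission_id)`.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return list with `stays` (raw, possibly split, input to
#'   [merge_admissions()]), `events` (raw: CPR/ECMO/EPI_BOLUS plus
#'   `INTUBATION` rows carrying `extubation_time`), `observations`
#'   (long-format med/lab/vital records) and `truth` (data frame of true
#'   confirmed events with `signature_onset`, plus the config as an
#'   attribute).
#' @export
generate_cohort <- function(config = synth_config(), seed = 1L) {
  cfg <- config
  origin <- .parse_time(paste0(cfg$period_start, " 00:00"))
  stays <- list(); events <- list(); obs <- list(); truth <- list()
  adm_counter <- 0L
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%05d", p)
    demo <- .with_seed(.derive_seed(seed, pid, "demo"), list(
      sex = .sample_cat(.demo_marginals$sex),
      race = .sample_cat(.demo_marginals$race),
      ethnicity = .sample_cat(.demo_marginals$ethnicity),
      insurance = .sample_cat(.demo_marginals$insurance),
      age = .sample_age(),
      n_adm = 1L + stats::rbinom(1, 1, cfg$readmission_prob)
    ))
    for (a in seq_len(demo$n_adm)) {
      adm_counter <- adm_counter + 1L
      aid <- sprintf("A%06d", adm_counter)
      g <- .generate_admission(cfg, seed, pid, aid, demo, origin)
      stays[[length(stays) + 1L]] <- g$stays
      if (!is.null(g$events)) events[[length(events) + 1L]] <- g$events
      if (!is.null(g$obs)) obs[[length(obs) + 1L]] <- g$obs
      if (!is.null(g$truth)) truth[[length(truth) + 1L]] <- g$truth
    }
  }
  empty_events <- data.frame(admission_id = character(),
                             event_type = character(),
                             event_time = as.POSIXct(character(), tz = "UTC"),
                             extubation_time = as.POSIXct(character(),
                                                          tz = "UTC"))
  out <- list(
    stays = do.call(rbind, stays),
    events = if (length(events)) do.call(rbind, events) else empty_events,
    observations = do.call(rbind, obs),
    truth = if (length(truth)) do.call(rbind, truth) else
      data.frame(admission_id = character(), event_type = character(),
                 event_time = as.POSIXct(character(), tz = "UTC"),
                 signature_onset = as.POSIXct(character(), tz = "UTC"))
  )
  rownames(out$stays) <- rownames(out$events) <- NULL
  rownames(out$observations) <- rownames(out$truth) <- NULL
  attr(out$truth, "config") <- cfg
  out
}

.generate_admission <- function(cfg, seed, pid, aid, demo, origin) {
  .with_seed(.derive_seed(seed, aid, "adm"), {
    start_off <- stats::runif(1, 0, cfg$period_days * 24)
    if (stats::runif(1) < cfg$short_stay_prob) {
      stay <- stats::runif(1, 6, cfg$min_stay_hours - 0.5)
    } else {
      repeat {
        stay <- stats::rlnorm(1, cfg$stay_meanlog, cfg$stay_sdlog)
        if (stay >= cfg$min_stay_hours) break
      }
    }
    stay <- round(stay * 60) / 60
    start_off <- round(start_off * 60) / 60
    picu_start <- origin + start_off * 3600
    picu_end <- picu_start + stay * 3600
    enc_start <- picu_start - round(stats::runif(1, 0, 48) * 60) / 60 * 3600

    # deterioration event (needs room: [16, stay - 2] non-empty)
    ev_type <- NA_character_; ev_t <- NA_real_
    if (stay >= cfg$min_stay_hours && stay - 2 > 16 &&
        stats::runif(1) < cfg$event_prob) {
      ev_t <- stats::runif(1, 16, stay - 2)
      ev_t <- round(ev_t * 60) / 60
      ev_type <- .sample_cat(cfg$event_mix)
    }
    onset <- if (!is.na(ev_t)) max(0, ev_t - cfg$lead_hours) else NA_real_

    ev_rows <- NULL
    truth_row <- NULL
    if (!is.na(ev_t)) {
      if (ev_type == "UEI") {
        dur <- stats::runif(1, 48, 240)
        ext <- if (ev_t + dur >= stay) as.POSIXct(NA) else
          picu_start + (ev_t + dur) * 3600
        ev_rows <- data.frame(admission_id = aid, event_type = "INTUBATION",
                              event_time = picu_start + ev_t * 3600,
                              extubation_time = ext,
                              stringsAsFactors = FALSE)
      } else {
        ev_rows <- data.frame(admission_id = aid, event_type = ev_type,
                              event_time = picu_start + ev_t * 3600,
                              extubation_time = as.POSIXct(NA),
                              stringsAsFactors = FALSE)
      }
      truth_row <- data.frame(admission_id = aid, event_type = ev_type,
                              event_time = picu_start + ev_t * 3600,
                              signature_onset = picu_start + onset * 3600,
                              stringsAsFactors = FALSE)
    }
    # elective intubation decoy: short, signature-free, rejected by the
    # 48-h rule; placed so extubation happens before discharge
    if (stay > 50 && stats::runif(1) < cfg$decoy_intubation_prob) {
      d_dur <- stats::runif(1, 4, 40)
      d_t <- stats::runif(1, 0.5, stay - d_dur - 1)
      ev_rows <- rbind(ev_rows, data.frame(
        admission_id = aid, event_type = "INTUBATION",
        event_time = picu_start + d_t * 3600,
        extubation_time = picu_start + (d_t + d_dur) * 3600,
        stringsAsFactors = FALSE))
    }

    # observation streams
    ob <- list()
    num_vars <- rbind(cbind(cfg$vitals, gap = cfg$vital_gap_mean),
                      cbind(cfg$labs, gap = cfg$lab_gap_mean))
    for (v in seq_len(nrow(num_vars))) {
      gaps <- stats::rexp(ceiling(stay / num_vars$gap[v] * 3) + 20,
                          1 / num_vars$gap[v])
      tt <- cumsum(gaps)
      tt <- round(tt[tt <= stay] * 60) / 60
      tt <- unique(tt)
      if (!length(tt)) next
      val <- num_vars$baseline[v] + .ar1_irregular(tt, num_vars$sd[v], cfg$ar) +
        .drift_at(tt, onset, ev_t,
                  cfg$effect * num_vars$sd[v] * num_vars$drift_sign[v])
      ob[[length(ob) + 1L]] <- data.frame(
        admission_id = aid, obs_time = picu_start + tt * 3600,
        variable = num_vars$variable[v], value = round(val, 3),
        category = if (v <= nrow(cfg$vitals)) "vital" else "laboratory",
        stringsAsFactors = FALSE)
    }
    for (m in cfg$medications) {
      # thinning: draw at the maximal rate, keep pre-event draws with the
      # boosted acceptance probability
      rmax <- cfg$med_base_rate * max(1, cfg$med_rate_multiplier)
      n_draw <- stats::rpois(1, rmax * stay)
      if (n_draw > 0) {
        tt <- sort(stats::runif(n_draw, 0, stay))
        in_sig <- !is.na(ev_t) & tt >= onset & tt <= ev_t
        rate <- ifelse(in_sig, cfg$med_base_rate * cfg$med_rate_multiplier,
                       cfg$med_base_rate)
        keep <- stats::runif(n_draw) < rate / rmax
        tt <- round(tt[keep] * 60) / 60
        tt <- unique(tt)
        if (length(tt))
          ob[[length(ob) + 1L]] <- data.frame(
            admission_id = aid, obs_time = picu_start + tt * 3600,
            variable = m, value = 1, category = "medication",
            stringsAsFactors = FALSE)
      }
    }

    # raw stays: occasionally split the admission into two stays with a
    # sub-24-h gap so the merge rule is exercised; observations and events
    # are defined on the merged timeline
    if (stay > 30 && stats::runif(1) < cfg$split_stay_prob) {
      cut <- round(stats::runif(1, 10, stay - 10) * 60) / 60
      gap <- round(stats::runif(1, 1, 20) * 60) / 60
      stay_rows <- data.frame(
        patient_id = pid, admission_id = c(aid, paste0(aid, "b")),
        encounter_id = paste0("E", aid),
        encounter_start = enc_start,
        picu_start = c(picu_start, picu_start + (cut + gap) * 3600),
        picu_end = c(picu_start + cut * 3600, picu_end + gap * 3600),
        age_years = demo$age, sex = demo$sex, race = demo$race,
        ethnicity = demo$ethnicity, insurance = demo$insurance,
        stringsAsFactors = FALSE)
    } else {
      stay_rows <- data.frame(
        patient_id = pid, admission_id = aid, encounter_id = paste0("E", aid),
        encounter_start = enc_start, picu_start = picu_start,
        picu_end = picu_end, age_years = demo$age, sex = demo$sex,
        race = demo$race, ethnicity = demo$ethnicity,
        insurance = demo$insurance, stringsAsFactors = FALSE)
    }
    list(stays = stay_rows, events = ev_rows,
         obs = if (length(ob)) do.call(rbind, ob) else NULL,
         truth = truth_row)
  })
}

#' Generate Bernoulli-exceedance risk scores
#'
#' Oracle input for the alert-burden simulator: at every grid point the
#' probability independently exceeds `ref_threshold` with probability `q`
#' (drawn uniform above the threshold on exceedance, uniform below
#' otherwise), so the alert process is a renewal process with closed-form
#' rate [expected_alert_rate()].
#'
#' @param admissions admission table (`admission_id`, `picu_start`,
#'   `picu_end`).
#' @param interval prediction-grid interval in hours.
#' @param q exceedance probability in `(0, 1]`.
#' @param seed integer seed.
#' @param ref_threshold the reference alert threshold (default 0.5).
#' @return long-format scores (`admission_id`, `time`, `probability`) with
#'   attribute `"ref_threshold"`.
#' @export
generate_bernoulli_scores <- function(admissions, interval, q, seed = 1L,
                                      ref_threshold = 0.5) {
  stopifnot(q > 0, q <= 1)
  out <- vector("list", nrow(admissions))
  for (i in seq_len(nrow(admissions))) {
    aid <- admissions$admission_id[i]
    g <- prediction_grid(admissions$picu_start[i], admissions$picu_end[i],
                         interval)
    p <- .with_seed(.derive_seed(seed, aid, "bern"), {
      exceed <- stats::runif(length(g)) < q
      ifelse(exceed,
             stats::runif(length(g), ref_threshold, 1),
             stats::runif(length(g), 0, ref_threshold - 1e-9))
    })
    out[[i]] <- data.frame(admission_id = aid, time = g, probability = p,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "ref_threshold") <- ref_threshold
  res
}

#' Closed-form renewal rate of the alert process
#'
#' For i.i.d. per-grid-point threshold exceedances with probability `q` on
#' a grid of spacing `interval`, with refractory `refractory`, the mean
#' alert cycle is `interval * max(1, ceiling(refractory / interval)) +
#' interval * (1/q - 1)` hours, giving `24 / cycle` alerts per patient-day
#' in the long-stay limit.
#'
#' @param interval grid spacing in hours.
#' @param q exceedance probability (`q = 0` returns rate 0).
#' @param refractory refractory period in hours.
#' @return expected alerts per patient-day.
#' @export
expected_alert_rate <- function(interval, q, refractory = 0) {
  stopifnot(interval > 0, q >= 0, q <= 1, refractory >= 0)
  if (q == 0) return(0)
  cycle <- interval * max(1, ceiling(refractory / interval)) +
    interval * (1 / q - 1)
  24 / cycle
}
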