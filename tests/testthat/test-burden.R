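scores_df <- function(times, probs, adm = "A1") {
  data.frame(admission_id = adm, time = times, probability = probs,
             stringsAsFactors = FALSE)
}

test_that("prediction grids cover the stay inclusively", {
  expect_equal(prediction_grid(0, 25, 12), c(0, 12, 24))
  expect_length(prediction_grid(0, 25, 1), 26)
  expect_equal(prediction_grid(0, 5, 12), 0)   # interval > stay
  expect_error(prediction_grid(10, 5, 1), "precedes")
})

test_that("alert firing honours threshold, refractory and censoring", {
  no_events <- make_events("zz", 1)[0, ]

  # saturated probabilities force the refractory cadence
  g <- prediction_grid(0, 36, 1)
  al <- simulate_alerts(scores_df(g, rep(1, length(g))), no_events,
                        alert_policy(interval = 1, threshold = 0.5,
                                     refractory = 12))
  expect_equal(al$alert_time, c(0, 12, 24, 36))

  # sub-threshold probabilities never fire
  al2 <- simulate_alerts(scores_df(g, rep(0.4, length(g))), no_events,
                         alert_policy(threshold = 0.5))
  expect_equal(nrow(al2), 0)

  # threshold comparison is >= by default, strict > by flag
  al3 <- simulate_alerts(scores_df(c(0, 1), c(0.5, 0.5)), no_events,
                         alert_policy(threshold = 0.5, refractory = 0))
  expect_equal(nrow(al3), 2)
  al4 <- simulate_alerts(scores_df(c(0, 1), c(0.5, 0.5)), no_events,
                         alert_policy(threshold = 0.5, strict = TRUE))
  expect_equal(nrow(al4), 0)

  # post-event censoring silences [e, e + censor)
  g48 <- prediction_grid(0, 48, 1)
  ev <- make_events("A1", 20)
  al5 <- simulate_alerts(scores_df(g48, rep(1, length(g48))), ev,
                         alert_policy(interval = 1, threshold = 0.5,
                                      refractory = 0, censor = 24))
  expect_equal(al5$alert_time, c(0:19, 44:48))

  # refractory blocks the open interval (a, a + R): eligible exactly at a+R
  al6 <- simulate_alerts(scores_df(c(0, 5.9, 6), c(1, 1, 1)), no_events,
                         alert_policy(threshold = 0.5, refractory = 6))
  expect_equal(al6$alert_time, c(0, 6))
})

test_that("detection uses the half-open 24-h look-back window", {
  ev <- make_events("A1", 30)
  mk <- function(at) data.frame(admission_id = "A1", alert_time = at,
                                probability = 1)
  expect_false(detection_fraction(mk(5), ev)$flags$detected)    # 25 h before
  expect_true(detection_fraction(mk(20), ev)$flags$detected)    # 10 h before
  expect_true(detection_fraction(mk(6), ev)$flags$detected)     # boundary in
  expect_false(detection_fraction(mk(30), ev)$flags$detected)   # at the event
  expect_true(is.na(detection_fraction(mk(5), ev[0, ])$fraction))

  # exhaustive pair-scan oracle on random instances
  set.seed(33)
  for (rep in 1:40) {
    al <- data.frame(admission_id = sample(c("A1", "A2"), 6, TRUE),
                     alert_time = runif(6, 0, 100), probability = 1)
    evr <- make_events(sample(c("A1", "A2"), 3, TRUE), runif(3, 0, 100))
    got <- detection_fraction(al, evr)$flags$detected
    want <- vapply(seq_len(3), function(i) {
      any(al$admission_id == evr$admission_id[i] &
            al$alert_time >= evr$event_time[i] - 24 &
            al$alert_time < evr$event_time[i])
    }, logical(1))
    expect_identical(got, want)
  }
})

test_that("burden metrics compute rates, leads and admission NNA", {
  adm <- make_admissions(c(0, 0), c(120, 120))
  ev <- make_events("A1", 100)
  al <- data.frame(admission_id = "A1", alert_time = c(80, 97),
                   probability = 1)
  pol <- alert_policy()
  rep <- burden_metrics(al, ev, adm, pol)
  expect_equal(rep$patient_days, 10)
  expect_equal(rep$alerts_per_patient_day, 0.2)
  expect_equal(rep$detection_fraction, 1)
  expect_equal(rep$lead_median, 20)   # earliest qualifying alert
  pol_l <- alert_policy(lead = "latest")
  expect_equal(burden_metrics(al, ev, adm, pol_l)$lead_median, 3)
  expect_equal(rep$admission_nna, 1)

  # NNA: flagged admissions over flagged-and-detected admissions
  adm10 <- make_admissions(rep(0, 10), rep(240, 10))
  ev10 <- make_events(paste0("A", 1:5), rep(100, 5))
  al10 <- data.frame(admission_id = paste0("A", 1:10),
                     alert_time = c(rep(90, 5), rep(200, 5)),
                     probability = 1)
  rep10 <- burden_metrics(al10, ev10, adm10, pol)
  expect_equal(rep10$admission_nna, 2)   # 10 flagged / 5 detected
  expect_equal(rep10$detection_fraction, 1)
})

test_that("admission NNA is the reciprocal admission-level PPV", {
  # window spanning the whole stay, at most one event per admission
  set.seed(61)
  adm <- make_admissions(rep(0, 25), rep(200, 25))
  has_ev <- rbinom(25, 1, 0.4) == 1
  ev <- make_events(adm$admission_id[has_ev],
                    runif(sum(has_ev), 150, 190))
  g200 <- prediction_grid(0, 200, 12)
  sc <- do.call(rbind, lapply(adm$admission_id, function(a)
    scores_df(g200, runif(length(g200)), adm = a)))
  pol <- alert_policy(interval = 12, threshold = 0.7, refractory = 0,
                      censor = 24, window = 200)
  al <- simulate_alerts(sc, ev, pol)
  rep <- burden_metrics(al, ev, adm, pol)
  flagged <- unique(al$admission_id)
  det <- detection_fraction(al, ev, window = 200)$flags
  ppv_adm <- length(intersect(flagged, det$admission_id[det$detected])) /
    length(flagged)
  expect_equal(rep$admission_nna, 1 / ppv_adm)
})

test_that("simulator matches the minute-resolution event-loop oracle", {
  set.seed(90)
  for (rep in 1:150) {
    stay <- sample(10:72, 1)
    interval <- sample(c(1, 2, 4, 12), 1)
    g <- prediction_grid(0, stay, interval)
    p <- round(runif(length(g)), 3)
    n_ev <- sample(0:3, 1)
    ev_t <- sort(round(runif(n_ev, 0, stay) * 60) / 60)
    pol <- alert_policy(interval = interval,
                        threshold = sample(c(0.2, 0.5, 0.8), 1),
                        refractory = sample(c(0, 5, 12), 1),
                        censor = sample(c(0, 12, 24), 1),
                        strict = sample(c(TRUE, FALSE), 1))
    ev <- if (n_ev) make_events("A1", ev_t) else make_events("x", 1)[0, ]
    got <- simulate_alerts(scores_df(g, p), ev, pol)$alert_time
    want <- oracle_alerts(g, p, ev_t, pol)
    expect_equal(got, want)
  }
})

test_that("alerts stay on the grid, apart, and out of censor windows", {
  set.seed(91)
  g <- prediction_grid(0, 200, 2)
  p <- runif(length(g))
  ev <- make_events("A1", c(50, 130))
  pol <- alert_policy(interval = 2, threshold = 0.4, refractory = 7,
                      censor = 24)
  al <- simulate_alerts(scores_df(g, p), ev, pol)
  expect_true(all(al$alert_time %in% g))
  expect_true(all(diff(al$alert_time) >= 7))
  for (e in c(50, 130))
    expect_false(any(al$alert_time >= e & al$alert_time < e + 24))
})

test_that("threshold sweeps are monotone and searchable", {
  set.seed(92)
  adm <- make_admissions(rep(0, 12), rep(150, 12))
  ev <- make_events(c("A1", "A2", "A3"), c(60, 90, 120))
  sc <- do.call(rbind, lapply(adm$admission_id, function(a)
    scores_df(prediction_grid(0, 150, 2), runif(76), adm = a)))
  pol <- alert_policy(interval = 2, refractory = 12)
  th <- seq(0.05, 0.95, by = 0.05)
  curve <- sweep_thresholds(sc, ev, adm, pol, th)
  expect_true(all(diff(curve$alerts_per_patient_day) <= 1e-12))
  expect_true(all(diff(curve$detection_fraction) <= 1e-12))

  # threshold 0: every grid point outside refractory/censor fires
  pol0 <- alert_policy(interval = 2, threshold = 0, refractory = 0,
                       censor = 0)
  al0 <- simulate_alerts(sc, ev, pol0)
  expect_equal(nrow(al0), nrow(sc))
  # threshold above every score: silence
  pol1 <- alert_policy(interval = 2, threshold = 1)
  expect_equal(nrow(simulate_alerts(sc, ev, pol1)), 0)

  pick <- threshold_for_detection(curve, 0.5)
  expect_gte(pick$report$detection_fraction, 0.5)
  # the picked threshold is the largest meeting the target
  larger <- curve$threshold > pick$threshold
  expect_true(all(curve$detection_fraction[larger] < 0.5 |
                    is.na(curve$detection_fraction[larger])))
  expect_error(threshold_for_detection(curve, 1.01), "unreachable")
  # target 0 is met by the largest threshold in the sweep
  expect_equal(threshold_for_detection(curve, 0)$threshold, max(th))
})

test_that("binary tool streams reuse the probability path unchanged", {
  adm <- make_admissions(0, 120)
  ev <- make_events("A1", 60)
  pol <- alert_policy(interval = 1, refractory = 12)
  g <- prediction_grid(0, 120, 1)

  ind0 <- data.frame(admission_id = "A1", time = g, value = 0)
  r0 <- binary_tool_burden(ind0, ev, adm, pol)
  expect_equal(r0$n_alerts, 0)
  expect_equal(r0$detection_fraction, 0)

  ind1 <- data.frame(admission_id = "A1", time = g, value = 1)
  r1 <- binary_tool_burden(ind1, ev, adm, pol)
  al_p <- simulate_alerts(scores_df(g, rep(1, length(g))), ev,
                          alert_policy(interval = 1, threshold = 0.5,
                                       refractory = 12))
  expect_equal(r1$n_alerts, nrow(al_p))

  set.seed(93)
  indr <- data.frame(admission_id = "A1", time = g,
                     value = rbinom(length(g), 1, 0.3))
  rr <- binary_tool_burden(indr, ev, adm, pol)
  rp <- burden_metrics(simulate_alerts(scores_df(g, indr$value), ev,
                                       alert_policy(interval = 1,
                                                    threshold = 0.5,
                                                    refractory = 12)),
                       ev, adm, alert_policy(interval = 1, threshold = 0.5,
                                             refractory = 12))
  expect_equal(rr$alerts_per_patient_day, rp$alerts_per_patient_day)
  expect_equal(rr$detection_fraction, rp$detection_fraction)

  ind_bad <- data.frame(admission_id = "A1", time = g, value = 0.5)
  expect_error(binary_tool_burden(ind_bad, ev, adm, pol), "binary")
})
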