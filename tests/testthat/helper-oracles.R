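# Independent oracles and small fixture builders shared across tests.
# Each oracle is a deliberately naive re-derivation (enumeration, minute
# loop, direct definition) kept independent of the package internals.

# AUROC by exhaustive positive-negative pair enumeration, ties half.
oracle_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Average precision via the explicit precision/recall ladder over
# descending distinct thresholds.
oracle_auprc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_rec <- 0
  for (th in thr) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n1
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

# Benjamini-Hochberg step-up by direct definition: find the largest k with
# p_(k) <= k/m * alpha; q-values as cumulative minima of m*p_(i)/i.
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- rev(cummin(rev(m * ps / seq_len(m))))
  qs <- pmin(qs, 1)
  q <- numeric(m); q[o] <- qs
  k <- which(ps <= seq_len(m) / m * alpha)
  reject <- rep(FALSE, m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  list(q = q, reject = reject)
}

# Minute-resolution event-loop alert simulator for one admission.
# Walks every minute of the stay, firing at grid minutes where the
# probability passes, outside the refractory and censor windows.
oracle_alerts <- function(times, probs, event_times, policy) {
  tm <- round(times * 60)
  em <- round(event_times * 60)
  lo <- min(tm); hi <- max(tm)
  p_at <- rep(NA_real_, hi - lo + 1)
  p_at[tm - lo + 1] <- probs
  cen <- rep(FALSE, hi - lo + 1)
  if (policy$censor > 0) {
    for (e in em) {
      lo_c <- max(lo, e)
      hi_c <- min(hi, e + policy$censor * 60 - 1)
      if (hi_c >= lo_c) cen[(lo_c:hi_c) - lo + 1] <- TRUE
    }
  }
  next_ok <- -Inf
  fired <- numeric(0)
  for (m in lo:hi) {
    p <- p_at[m - lo + 1]
    if (is.na(p)) next
    pass <- if (policy$strict) p > policy$threshold else p >= policy$threshold
    if (!pass || m < next_ok || cen[m - lo + 1]) next
    fired <- c(fired, m / 60)
    next_ok <- m + policy$refractory * 60
  }
  fired
}

# Jackknife variance of the AUROC (leave-one-out over all samples).
oracle_jackknife_auc_var <- function(scores, labels) {
  n <- length(scores)
  loo <- vapply(seq_len(n), function(i)
    auroc(scores[-i], labels[-i]), numeric(1))
  (n - 1) / n * sum((loo - mean(loo))^2)
}

# Minimal admission table: numeric hours, ids A1, A2, ...
make_admissions <- function(starts, ends, patient = NULL, age = 5,
                            sex = "F") {
  n <- length(starts)
  data.frame(
    patient_id = if (is.null(patient)) paste0("pt", seq_len(n)) else patient,
    admission_id = paste0("A", seq_len(n)),
    encounter_id = paste0("E", seq_len(n)),
    encounter_start = starts, picu_start = starts, picu_end = ends,
    age_years = age, sex = sex, race = "White", ethnicity = "NonHispanic",
    insurance = "Private", stringsAsFactors = FALSE)
}

make_events <- function(admission_id, times, type = "CPR") {
  data.frame(admission_id = admission_id, event_type = type,
             event_time = times, extubation_time = NA_real_,
             stringsAsFactors = FALSE)
}

# A small trained ensemble + matrices reused across ensemble/metric tests
# (built once per test run; strong separable signal).
fixture_trained <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    syn <- generate_cohort(synth_config(n_patients = 90, effect = 4,
                                        split_stay_prob = 0,
                                        decoy_intubation_prob = 0),
                           seed = 401)
    coh <- apply_inclusion(merge_admissions(syn$stays))
    cde <- confirm_cde(syn$events, coh)
    smp <- build_training_samples(coh, cde, seed = 7)
    spec <- default_feature_spec()
    mat <- build_matrix(smp, syn$observations, coh, spec)
    ens <- train_ensemble(
      smp, mat$x, coh,
      learner_spec(grid = data.frame(max_depth = 3, eta = 0.3, nrounds = 20,
                                     min_child_weight = 1)),
      seed = 11, cv = FALSE)
    cache <<- list(syn = syn, coh = coh, cde = cde, smp = smp, spec = spec,
                   mat = mat, ens = ens)
    cache
  }
})
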