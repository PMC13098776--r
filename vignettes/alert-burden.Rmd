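---
title: "Deterioration prediction and alert-burden emulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterioration prediction and alert-burden emulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Early-warning systems in the pediatric ICU aim to flag patients hours
before a *critical deterioration event* (CDE) — cardiopulmonary
resuscitation, ECMO initiation, a dilute-epinephrine bolus, or an
unplanned endotracheal intubation (UEI) — so that teams can prepare rather
than rescue. Two questions decide whether such a system is usable at the
bedside: *does the risk score discriminate far enough ahead of the
event?* and *how many alerts does a deployment actually generate per
patient-day?* `picuews` implements both halves: multi-horizon ensemble
risk modeling, and a deterministic deployment emulation that converts any
risk score (or an existing binary tool's alert stream) into burden,
detection and lead-time metrics.

## Cohort and event construction

Raw PICU stays are merged into continuous admissions when a patient
leaves the unit for under 24 h within one hospital encounter
(`merge_admissions()`); the cohort keeps admissions of at least 24 h and
ages 0–24 years (`apply_inclusion()`, upper bound exclusive at 25 so
24-year-olds remain eligible). Event rules (`confirm_cde()`):

* an intubation is a **UEI** only when it persists ≥ 48 h, a proxy that
  removes elective and procedural airway management; intubations still
  ongoing at discharge are confirmed and flagged (`ongoing_at_end`) for
  sensitivity analysis, since death or transfer censors the persistence
  observation;
* events within 8 h of a prior event are one deterioration trajectory —
  a greedy chronological pass keeps an event only if it falls at least
  8 h after the last *kept* event. Anchoring on kept events (rather than
  on every raw event) is the default because it reproduces the canonical
  worked case — CPR followed an hour later by ECMO cannulation retains
  only the CPR — with a single deterministic pass; the raw-anchoring
  convention is available via `anchor = "raw"`. A gap of exactly 8 h is
  retained.

Temporal validation uses `temporal_split()`: admissions starting at or
after a boundary date enter validation only when their hospital encounter
also started after it. Straddling encounters are excluded from both
sets rather than folded into development — including post-boundary
admissions in training would leak future-period data.

Training samples (`build_training_samples()`): each retained CDE yields
one positive snapshot per horizon at `event − h` for
`h ∈ {1, 2, 4, 6, 8, 12}` h; events inside the first 16 h of the stay
are not training targets (baseline data availability); each event-free
admission contributes a single control time drawn uniformly at 1-minute
resolution from the closed interval `[start + 16 h, end − 6 h]`, shared
across horizons (drawing one control per admission is the down-sampling
that keeps class imbalance workable while admission-level stratification
limits leakage). Control draws are seeded per admission by hashing
`(seed, admission_id)`, so editing the cohort never reshuffles unrelated
admissions.

## Feature snapshots

`extract_snapshot()` turns an irregular observation stream into a fixed
vector at time `t` using only observations with `obs_time ≤ t`. Windows
are half-open `(t − w, t]` with defaults `w ∈ {6, 24}` h. Per vital/lab
variable and window: last, mean, min, max, least-squares slope per hour
(missing with fewer than two distinct time points), observation *rate*,
and hours since the last measurement; per medication and window: an
administration rate and an any-given indicator; plus age and sex. Missing
summaries are `NA`, which the tree learners consume natively; no
imputation is applied by default (the random-forest and lasso backends
impute training medians internally).

Two numerical choices deserve explanation:

* **Duplicate timestamps** keep the last-recorded value; slopes with a
  zero-variance time vector are missing.
* **Counts are rates.** A raw count over a window that is truncated by
  the admission start is a proxy for time-since-admission. Positive
  snapshots (`event − h` with events allowed from hour 16) can fall
  earlier in a stay than control snapshots (never before hour 16), so any
  position-encoding feature would let a flexible learner separate the
  classes even with no physiologic signal. Normalising counts by the
  in-stay width of the window makes their expectation
  position-invariant. Residual position coupling survives in the
  missingness pattern and the recency tails of sparse streams; on null
  cohorts (effect size 0) this residue is small — pooled validation AUROC
  centred near 0.5 (roughly 0.50–0.54 on repeated cohort draws) rather
  than the ≈ 0.60 observed with raw counts — but it is not exactly zero,
  and it is the main caveat when interpreting near-chance AUROCs from
  this pipeline.

The scheme is deliberately generic — a stand-in for any site-specific
feature dictionary — and `feature_spec()` lets users substitute richer
variable sets without touching the rest of the pipeline.

## The multi-horizon ensemble

One classifier per horizon is trained on that horizon's positives plus
the shared controls; the deployed risk index is the arithmetic mean of
the six member probabilities (`predict_ensemble()`), hence invariant to
member order and bounded in `[0, 1]`. Learner families: gradient-boosted
trees (default, `xgboost`), random forest (`ranger`) and L1-regularised
logistic regression (`glmnet`), all behind one fit/predict-probability
contract so the pipeline is family-agnostic. Hyperparameters are chosen
by mean held-out AUROC over ten stratified cross-validation folds grouped
by *patient* (the stricter leakage guard; admission-level grouping is a
flag). The default grid is deliberately small — desk-scale runtimes —
and user-expandable.

Parsimonious variants (`select_parsimonious()`) rank features per horizon
by plug-in mutual information with the label (equal-frequency 10-bin
discretisation for continuous features, missing values as their own bin —
mirroring what a tree sees; discrete features with at most `bins`
distinct values are used as-is) and keep the top *k*; the union over the
six horizons is the parsimonious dictionary. The plug-in estimator is
deterministic and dependency-free; ranking, not unbiased estimation, is
what matters here.

## Evaluation statistics

* `auroc()` is the Mann–Whitney statistic with mid-rank ties, making it
  consistent with the DeLong machinery; `auprc()` is average precision
  over recall change points.
* `bootstrap_ci()` resamples positives and negatives independently
  (stratified), 2000 replicates by default, percentile interval. The
  percentile flavour is the minimal-assumption choice; BCa is
  deliberately out of scope.
* `delong_test()` implements the paired AUROC comparison through
  placement values; identical scores give p = 1 by convention. Subgroup
  (fairness) comparisons in `fairness_report()` instead use an *unpaired*
  z-test built from per-group DeLong variances — disjoint subgroups are
  independent samples, so the paired covariance does not apply. Subgroups
  with one class are flagged not-evaluable and excluded from the
  Benjamini–Hochberg family (`bh_adjust()`).
* `operating_points()` picks, for each sensitivity target, the largest
  threshold whose sensitivity meets it, and reports the sample-level
  number needed to alert `NNA = 1/PPV`.

## Deployment emulation: alert burden

This is the package's core. A risk series on a regular grid over the
*entire* stay (`prediction_grid()`, `score_admissions()`) is scanned
chronologically (`simulate_alerts()`): an alert fires at grid time `t`
when the probability meets the threshold (`≥` by default so that binary
0/1 streams behave identically at threshold 0.5; strict `>` is a flag),
`t` is not within the refractory period of the previous fired alert
(open interval `(a, a + R)`; the refractory re-anchors on each fired
alert), and `t` is not inside any event's censoring window
`[e, e + 24 h)` — alerts after the event carry no preparatory value.
Conventions, all half-open and all tested against a minute-resolution
event-loop oracle:

* detection window `[e − 24 h, e)`: an alert at the event instant is not
  advance warning;
* alerts may resume exactly 24 h after an event, and exactly `R` hours
  after an alert;
* lead time uses the *earliest* qualifying alert (maximal preparation
  time; `lead = "latest"` is available);
* the patient-day denominator is the full stay, censored and refractory
  time included — "alerts per patient-day" with no stated exclusion;
* *all* confirmed events, including those in the first 16 h of a stay,
  count here (in contrast to model training).

`burden_metrics()` reports alerts per patient-day, the detected fraction,
median/IQR lead time, and the admission-level NNA (admissions with ≥ 1
alert per admission with both an alert and a detected event — the
reciprocal of admission-level PPV). `sweep_thresholds()` traces the
detection-versus-burden tradeoff; `threshold_for_detection()` returns the
largest (minimal-burden) threshold meeting a detection target;
`binary_tool_burden()` pushes an existing rule-based tool's hourly 0/1
indicator through the identical path for a like-for-like comparison.

Alerts per patient-day is provably non-increasing in the threshold and
the alert count non-increasing in the refractory period (each alert time
can only shift later); the sweep enforces the former. The detection
fraction can, in contrived configurations with a refractory period,
*increase* with the threshold — a suppressed low-threshold alert can
occupy the refractory slot that a later, window-qualifying alert needed —
so the sweep only warns on such wobbles rather than failing.

With i.i.d. per-grid-point exceedance probability `q`, spacing `Δ` and
refractory `R`, the alert process is a renewal process with mean cycle
`Δ·max(1, ⌈R/Δ⌉) + Δ(1/q − 1)` hours (`expected_alert_rate()`); the test
suite checks the simulator against this closed form after a 240-h burn-in
(the closed form is the steady-state rate; counting from admission start
would inflate the empirical rate by the first cycle's head start).

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a single-centre PICU
cohort so every stage is testable without patient data: log-normal stays
(median 96 h — chosen so the implied mean stay of roughly eight
patient-days matches a validation cohort of ~60,000 patient-days over
~7,000 admissions); a 5% event-admission rate (realistic range 4–6%);
event types drawn as 14% CPR / 1% ECMO / 34% epinephrine bolus / 51% UEI;
demographics sampled from published marginal frequencies (56% female,
etc.) with *zero* association with events by construction, so fairness
analyses have a known null; occasional split stays and sub-48-h "decoy"
elective intubations to exercise the merge and UEI rules end to end.

Observation streams are AR(1) processes (per-hour autocorrelation 0.8,
exact discretisation over exponential inter-observation gaps — mean 1 h
for vitals, 8 h for labs) around per-variable baselines. The
deterioration signature is a *linear drift* of standardized magnitude
`effect` (δ) per variable, beginning `lead_hours` (τ, default 12 h)
before the event, held after it; heart/respiratory rate and lactate rise,
blood pressure and oxygen saturation fall; medication administration
rates scale by `1 + 0.25·δ` in the same window, so δ = 0 is a fully null
signature. A linear ramp (not a step) gives horizon models graded signal
by lead time, mirroring the qualitative horizon ordering seen in real
deterioration data. Note the corollary: with τ = 12 h the 12-h-horizon
snapshot sits exactly at signature onset and is *informationless by
construction* — near-chance AUROC and an AUPRC near prevalence at that
horizon are the correct generator-consistent outcome, not a defect. What
the generator does **not** emulate: real waveform structure,
pharmacology, unit practice patterns, feature dictionaries of real EHRs —
so passing tests show pipeline correctness, not clinical performance.

## Scale of the bundled checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen once:
1000 random simulator instances against the minute-loop oracle; renewal
checks over 500 stays per `(Δ, R, q)` cell; DeLong null calibration over
1000 simulated pairs at n = 500; end-to-end signature recovery on
1000-patient cohorts (δ = 3 versus δ = 0, single-configuration
gradient-boosting grid with cross-validation off — the CV path is
exercised separately on smaller data); the acceptance script uses
800-patient development and 500-patient validation cohorts and a 2-h
prediction grid. At these sizes the pooled null AUROC fluctuates by a few
hundredths across cohort draws (a few dozen event clusters dominate the
variance); the reported `n` fields make that precision explicit.

## Known limitations

* No clinician-response modeling: alerts do not change the simulated
  trajectory, acknowledgment and feedback loops are out of scope.
* No calibration layer or calibration metrics; discrimination and burden
  only.
* The residual snapshot-position coupling described above bounds how
  exactly "null" a null cohort can look to a flexible learner.
* Real-data performance claims cannot be reproduced from synthetic
  cohorts; the generator validates machinery, not models.
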