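#' Define a windowed feature extraction scheme
#'
#' Describes how irregular observation streams are summarised into a
#' fixed-length vector at a snapshot time.  For every vital-sign and
#' laboratory variable and lookback window the scheme produces seven
#' summaries (`last`, `mean`, `min`, `max`, `slope` in units per hour,
#' measurement count `n`, and `hrs_since` the most recent measurement in
#' the window); for every medication and window it produces the
#' administration count `n` and an `any`-given indicator.  Two demographic
#' features (age in years and a female-sex indicator) complete the vector,
#' so the total length is `7 * (#vitals + #labs) * #windows +
#' 2 * #medications * #windows + 2`.
#'
#' @param vitals,labs,medications character vectors of variable names.
#' @param windows lookback windows in hours (default `c(6, 24)`); windows
#'   are half-open `(t - w, t]` so an observation exactly at the snapshot
#'   is included.
#' @return an object of class `feature_spec`.
#' @seealso [extract_snapshot()], [build_matrix()]
#' @export
feature_spec <- function(vitals = character(), labs = character(),
                         medications = character(), windows = c(6, 24)) {
  stopifnot(all(windows > 0))
  spec <- structure(list(vitals = vitals, labs = labs,
                         medications = medications, windows = windows),
                    class = "feature_spec")
  spec$names <- .feature_names(spec)
  spec
}

.num_summaries <- c("last", "mean", "min", "max", "slope", "rate", "hrs_since")
.med_summaries <- c("rate", "any")

.feature_names <- function(spec) {
  nm <- character(0)
  for (v in c(spec$vitals, spec$labs))
    for (w in spec$windows)
      nm <- c(nm, paste(v, paste0("w", w), .num_summaries, sep = "."))
  for (m in spec$medications)
    for (w in spec$windows)
      nm <- c(nm, paste(m, paste0("w", w), .med_summaries, sep = "."))
  c(nm, "age_years", "sex_female")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("Feature spec:", length(x$names), "features (",
      length(x$vitals), "vitals,", length(x$labs), "labs,",
      length(x$medications), "medications; windows",
      paste(x$windows, collapse = "/"), "h )\n")
  invisible(x)
}

#' Feature spec matching the bundled synthetic generator
#'
#' @param windows lookback windows in hours.
#' @return a [feature_spec()] covering the variables emitted by
#'   [generate_cohort()].
#' @export
default_feature_spec <- function(windows = c(6, 24)) {
  feature_spec(
    vitals = c("heart_rate", "resp_rate", "sbp", "spo2"),
    labs = c("lactate", "wbc", "creatinine"),
    medications = c("sedative", "vasopressor"),
    windows = windows
  )
}

# Index observations by admission and variable for fast repeated snapshots.
# Returns env: admission_id -> list(variable -> list(t = hours, v = value)).
.obs_index <- function(observations) {
  idx <- new.env(parent = emptyenv())
  if (nrow(observations) == 0) return(idx)
  t <- .as_hours(observations$obs_time)
  split_adm <- split(seq_len(nrow(observations)), observations$admission_id)
  for (adm in names(split_adm)) {
    ii <- split_adm[[adm]]
    by_var <- split(ii, observations$variable[ii])
    lst <- lapply(by_var, function(jj) {
      # sort by time; ties broken by row order so the last-recorded value
      # wins when timestamps are duplicated
      o <- order(t[jj])
      list(t = t[jj][o], v = observations$value[jj][o])
    })
    assign(adm, lst, envir = idx)
  }
  idx
}

# `overlap` is the in-stay width of the lookback window in hours; counts
# are reported per overlap-hour so a window truncated by the admission
# start has the same expected rate as a full one (snapshot-position
# invariance; see the methods vignette).
.summarise_numeric <- function(tt, vv, t, w, overlap = w) {
  sel <- tt > t - w & tt <= t
  if (!any(sel))
    return(c(last = NA_real_, mean = NA_real_, min = NA_real_,
             max = NA_real_, slope = NA_real_, rate = 0,
             hrs_since = NA_real_))
  ts <- tt[sel]; vs <- vv[sel]
  # duplicate timestamps: keep the last-recorded value
  if (anyDuplicated(ts)) {
    keep <- !duplicated(ts, fromLast = TRUE)
    ts <- ts[keep]; vs <- vs[keep]
  }
  n <- length(ts)
  slope <- NA_real_
  if (n >= 2) {
    tc <- ts - mean(ts)
    den <- sum(tc^2)
    slope <- if (den > 0) sum(tc * (vs - mean(vs))) / den else NA_real_
  }
  c(last = vs[n], mean = mean(vs), min = min(vs), max = max(vs),
    slope = slope, rate = n / overlap, hrs_since = t - ts[n])
}

.summarise_med <- function(tt, t, w, overlap = w) {
  n <- sum(tt > t - w & tt <= t)
  c(rate = n / overlap, any = as.numeric(n > 0))
}

#' Extract a feature vector at a snapshot time
#'
#' Summarises every variable of `spec` over each lookback window ending at
#' `t`, using only observations with `obs_time <= t` (strictly causal).
#' Variables never observed in a window get the missing code `NA` for the
#' value summaries and 0 for counts.
#'
#' @param observations long-format observations of one admission
#'   (`obs_time`, `variable`, `value`); rows of other variables are
#'   ignored.
#' @param t snapshot time (same clock as `obs_time`).
#' @param spec a [feature_spec()].
#' @param age_years,sex demographics; `sex` is `"F"`/`"M"` (or 1/0).
#' @param admission_start optional stay start; when supplied, observation
#'   rates are normalised by the in-stay width of each window (counts per
#'   hour), so windows truncated by the admission start are comparable to
#'   full ones.
#' @return named numeric vector of length `length(spec$names)`.
#' @export
extract_snapshot <- function(observations, t, spec, age_years, sex,
                             admission_start = NULL) {
  by_var <- NULL
  if (nrow(observations) > 0) {
    tt <- .as_hours(observations$obs_time)
    by_var <- lapply(split(seq_len(nrow(observations)),
                           observations$variable),
                     function(jj) {
                       o <- order(tt[jj])
                       list(t = tt[jj][o], v = observations$value[jj][o])
                     })
  }
  .snapshot_from_index(by_var, .as_hours(t), spec, age_years, sex,
                       start = if (is.null(admission_start)) NULL else
                         .as_hours(admission_start))
}

.snapshot_from_index <- function(by_var, t, spec, age_years, sex,
                                 start = NULL) {
  overlap_of <- function(w) {
    if (is.null(start)) w else min(w, max(t - start, 1 / 60))
  }
  out <- numeric(0)
  for (v in c(spec$vitals, spec$labs)) {
    s <- by_var[[v]]
    for (w in spec$windows) {
      out <- c(out, if (is.null(s))
        c(NA, NA, NA, NA, NA, 0, NA) else
          .summarise_numeric(s$t, s$v, t, w, overlap_of(w)))
    }
  }
  for (m in spec$medications) {
    s <- by_var[[m]]
    for (w in spec$windows) {
      out <- c(out, if (is.null(s)) c(0, 0) else
        .summarise_med(s$t, t, w, overlap_of(w)))
    }
  }
  sexf <- if (is.numeric(sex)) as.numeric(sex) else as.numeric(sex %in% "F")
  out <- c(out, age_years, sexf)
  names(out) <- spec$names
  out
}

#' Build a feature matrix for a set of snapshot samples
#'
#' Rows follow the order of `samples`; columns follow the deterministic
#' ordering of `spec`.  Missing summaries are encoded `NA` (tree learners
#' consume them natively).
#'
#' @param samples data frame with `admission_id`, `snapshot_time` and
#'   (optionally) `label` — e.g. the output of [build_training_samples()].
#' @param observations long-format observation table for the cohort.
#' @param admissions admission table supplying `age_years` and `sex`.
#' @param spec a [feature_spec()].
#' @return list with `x` (numeric matrix), `y` (labels or `NULL`) and
#'   `feature_names`.
#' @export
build_matrix <- function(samples, observations, admissions, spec) {
  .require_cols(samples, c("admission_id", "snapshot_time"), "samples")
  unknown <- setdiff(samples$admission_id, admissions$admission_id)
  if (length(unknown))
    .stopf("samples reference unknown admission(s): %s",
           paste(utils::head(unknown, 3), collapse = ", "))
  idx <- .obs_index(observations)
  known_vars <- c(spec$vitals, spec$labs, spec$medications)
  extra <- setdiff(unique(observations$variable), known_vars)
  if (length(extra))
    .warnf("ignoring %d observation variable(s) not in the feature spec: %s",
           length(extra), paste(utils::head(extra, 5), collapse = ", "))
  mi <- match(samples$admission_id, admissions$admission_id)
  age <- admissions$age_years[mi]
  sex <- admissions$sex[mi]
  starts <- .as_hours(admissions$picu_start)[mi]
  tt <- .as_hours(samples$snapshot_time)
  x <- matrix(NA_real_, nrow(samples), length(spec$names),
              dimnames = list(NULL, spec$names))
  for (i in seq_len(nrow(samples))) {
    by_var <- if (exists(samples$admission_id[i], envir = idx))
      get(samples$admission_id[i], envir = idx) else NULL
    x[i, ] <- .snapshot_from_index(by_var, tt[i], spec, age[i], sex[i],
                                   start = starts[i])
  }
  list(x = x, y = if ("label" %in% names(samples)) samples$label else NULL,
       feature_names = spec$names)
}
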