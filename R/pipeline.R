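#' Read the standard input tables
#'
#' CSV readers for the interchange tables (ISO-8601 timestamps, UTC).
#'
#' @param path file path.
#' @return data frame with timestamp columns parsed to POSIXct.
#' @name readers
NULL

#' @rdname readers
#' @export
read_admissions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("patient_id", "admission_id", "encounter_id",
                      "encounter_start", "picu_start", "picu_end",
                      "age_years"), "admissions.csv")
  for (col in c("encounter_start", "picu_start", "picu_end"))
    df[[col]] <- .parse_time(df[[col]])
  df
}

#' @rdname readers
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("admission_id", "event_type", "event_time"),
                "events.csv")
  df$event_time <- .parse_time(df$event_time)
  if (!is.null(df$extubation_time)) {
    df$extubation_time[df$extubation_time == ""] <- NA
    df$extubation_time <- .parse_time(df$extubation_time)
  }
  df
}

#' @rdname readers
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("admission_id", "obs_time", "variable", "value",
                      "category"), "observations.csv")
  df$obs_time <- .parse_time(df$obs_time)
  df
}

#' @rdname readers
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("admission_id", "time", "probability"), "scores.csv")
  if (is.character(df$time)) df$time <- .parse_time(df$time)
  df
}

.known_event_types <- c("CPR", "ECMO", "EPI_BOLUS", "UEI", "INTUBATION")

#' Validate the input tables
#'
#' Checks column presence, timestamp ordering, referential integrity
#' (events and observations must reference known admissions and fall
#' inside their stay), event-type and category domains, and value
#' finiteness.  Returns a row-level issue report; an empty report means
#' the tables are well-formed.
#'
#' @param admissions,events,observations parsed tables (see `readers`).
#' @return data frame with columns `table`, `row`, `issue`.
#' @export
validate_tables <- function(admissions, events = NULL, observations = NULL) {
  issues <- list()
  add <- function(tbl, row, msg)
    issues[[length(issues) + 1L]] <<- data.frame(table = tbl, row = row,
                                                 issue = msg,
                                                 stringsAsFactors = FALSE)
  bad <- which(.as_hours(admissions$picu_end) <=
                 .as_hours(admissions$picu_start))
  for (i in bad) add("admissions", i, "picu_end <= picu_start")
  bad <- which(admissions$age_years < 0)
  for (i in bad) add("admissions", i, "negative age")
  start <- .as_hours(admissions$picu_start)
  end <- .as_hours(admissions$picu_end)
  aid <- admissions$admission_id
  if (anyDuplicated(aid))
    add("admissions", anyDuplicated(aid), "duplicated admission_id")
  if (!is.null(events) && nrow(events)) {
    mi <- match(events$admission_id, aid)
    for (i in which(is.na(mi)))
      add("events", i, "unknown admission_id")
    tt <- .as_hours(events$event_time)
    ok <- !is.na(mi)
    for (i in which(ok & (tt < start[mi] | tt > end[mi])))
      add("events", i, "event_time outside admission stay")
    for (i in which(!events$event_type %in% .known_event_types))
      add("events", i, paste0("unknown event_type '", events$event_type[i], "'"))
  }
  if (!is.null(observations) && nrow(observations)) {
    mi <- match(observations$admission_id, aid)
    for (i in which(is.na(mi)))
      add("observations", i, "unknown admission_id")
    tt <- .as_hours(observations$obs_time)
    ok <- !is.na(mi)
    for (i in which(ok & (tt < start[mi] | tt > end[mi])))
      add("observations", i, "obs_time outside admission stay")
    for (i in which(!is.finite(observations$value)))
      add("observations", i, "non-finite value")
    for (i in which(!observations$category %in%
                      c("medication", "laboratory", "vital")))
      add("observations", i, "unknown category")
  }
  if (!length(issues))
    return(data.frame(table = character(), row = integer(),
                      issue = character()))
  do.call(rbind, issues)
}

#' Score admissions on a prediction grid
#'
#' Computes the ensemble risk index on a regular grid over each
#' admission's full stay — the risk series that feeds the alert-burden
#' simulation.
#'
#' @param ensemble a fitted [train_ensemble()] model.
#' @param admissions admissions to score.
#' @param observations their observation streams.
#' @param spec the [feature_spec()] used at training.
#' @param interval prediction interval in hours.
#' @return long-format risk series (`admission_id`, `time` in hours on the
#'   absolute clock, `probability`).
#' @export
score_admissions <- function(ensemble, admissions, observations, spec,
                             interval = 1) {
  grids <- lapply(seq_len(nrow(admissions)), function(i)
    prediction_grid(admissions$picu_start[i], admissions$picu_end[i],
                    interval))
  snap <- data.frame(
    admission_id = rep(admissions$admission_id, lengths(grids)),
    snapshot_time = unlist(grids), stringsAsFactors = FALSE)
  mat <- build_matrix(snap, observations, admissions, spec)
  data.frame(admission_id = snap$admission_id, time = snap$snapshot_time,
             probability = predict_ensemble(ensemble, mat$x),
             stringsAsFactors = FALSE)
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")

.write_table <- function(df, path) {
  for (col in names(df))
    if (inherits(df[[col]], "POSIXct")) df[[col]] <- .fmt_time(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Run the full analysis pipeline
#'
#' Executes cohort construction, event confirmation, temporal split,
#' feature extraction, ensemble training, validation-set evaluation and
#' the deployment-emulating alert-burden sweep, writing versioned
#' artifacts (CSV/JSON plus a manifest with parameters and seed) to
#' `out_dir`.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   `input` (paths to `admissions`, `events`, `observations` CSVs) *or*
#'   `synth` (a list of [synth_config()] arguments to generate data);
#'   `split_boundary` (timestamp string; default: the 70% quantile of
#'   PICU start times); `horizons`; `learner` (arguments of
#'   [learner_spec()]); `policy` (arguments of [alert_policy()]);
#'   `thresholds` (sweep grid); `detection_target` (default 0.8);
#'   `score_interval` (default 2); `cv` (default `FALSE`); `seed`.
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @return invisibly, a list with the cohort, split, model, metrics and
#'   burden results.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(seed)) seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$input)) {
    stays <- read_admissions(config$input$admissions)
    events_raw <- read_events(config$input$events)
    observations <- read_observations(config$input$observations)
  } else {
    syn <- generate_cohort(do.call(synth_config, config$synth %||% list()),
                           seed = seed)
    stays <- syn$stays
    events_raw <- syn$events
    observations <- syn$observations
  }

  # cohort construction
  merged <- merge_admissions(stays)
  cohort <- apply_inclusion(merged)
  flow <- attr(cohort, "flow")
  issues <- validate_tables(cohort,
                            events_raw[events_raw$admission_id %in%
                                         cohort$admission_id, , drop = FALSE],
                            NULL)
  if (nrow(issues)) {
    .write_table(issues, file.path(out_dir, "validation_issues.csv"))
    .stopf("input validation failed: %d issue(s), first: %s (see validation_issues.csv)",
           nrow(issues), issues$issue[1])
  }
  cde <- confirm_cde(events_raw, cohort)
  .write_table(cohort, file.path(out_dir, "cohort.csv"))
  .write_table(cde, file.path(out_dir, "cde_confirmed.csv"))
  .write_json(flow, file.path(out_dir, "flowchart.json"))

  boundary <- config$split_boundary %||%
    .fmt_time(as.POSIXct(stats::quantile(as.numeric(cohort$picu_start), 0.7),
                         tz = "UTC", origin = "1970-01-01"))
  split <- temporal_split(cohort, boundary)
  dev <- cohort[cohort$admission_id %in% split$development, , drop = FALSE]
  val <- cohort[cohort$admission_id %in% split$validation, , drop = FALSE]

  horizons <- config$horizons %||% c(1, 2, 4, 6, 8, 12)
  samples_dev <- build_training_samples(dev, cde, horizons = horizons,
                                        seed = .derive_seed(seed, "dev", "samples"))
  samples_val <- build_training_samples(val, cde, horizons = horizons,
                                        seed = .derive_seed(seed, "val", "samples"))
  spec <- default_feature_spec()
  mat_dev <- build_matrix(samples_dev, observations, dev, spec)
  mat_val <- build_matrix(samples_val, observations, val, spec)
  .write_table(samples_dev, file.path(out_dir, "samples.csv"))
  .write_json(list(feature_names = spec$names),
              file.path(out_dir, "features_schema.json"))

  lspec <- do.call(learner_spec, config$learner %||% list())
  ens <- train_ensemble(samples_dev, mat_dev$x, dev, lspec,
                        horizons = horizons, seed = seed,
                        cv = isTRUE(config$cv))

  # validation-set evaluation: ensemble risk index on horizon-labelled
  # snapshots; per-horizon AUROC/AUPRC over that horizon's positives plus
  # the shared controls
  p_val <- predict_ensemble(ens, mat_val$x)
  metrics <- list()
  for (h in horizons) {
    sel <- is.na(samples_val$horizon) | samples_val$horizon == h
    y <- samples_val$label[sel]
    if (length(unique(y)) < 2) next
    metrics[[paste0("h", h)]] <- list(
      auroc = auroc(p_val[sel], y), auprc = auprc(p_val[sel], y),
      n = sum(sel))
  }
  .write_json(metrics, file.path(out_dir, "metrics.json"))

  # deployment emulation on the validation cohort
  interval <- config$score_interval %||% 2
  policy <- do.call(alert_policy, utils::modifyList(
    list(interval = interval), config$policy %||% list()))
  series <- score_admissions(ens, val, observations, spec,
                             interval = interval)
  val_events <- cde[cde$admission_id %in% val$admission_id, , drop = FALSE]
  thresholds <- config$thresholds %||% seq(0.02, 0.98, by = 0.04)
  curve <- sweep_thresholds(series, val_events, val, policy, thresholds)
  .write_table(as.data.frame(curve)[, 1:7], file.path(out_dir, "sweep.csv"))
  target <- config$detection_target %||% 0.8
  burden <- tryCatch(threshold_for_detection(curve, target),
                     error = function(e) NULL)
  if (!is.null(burden)) {
    b <- burden$report
    .write_json(list(detection_target = target, threshold = burden$threshold,
                     alerts_per_patient_day = b$alerts_per_patient_day,
                     detection_fraction = b$detection_fraction,
                     lead_median = b$lead_median,
                     lead_iqr = b$lead_iqr, admission_nna = b$admission_nna),
                file.path(out_dir, "burden.json"))
  }
  .write_json(list(seed = seed, boundary = boundary, horizons = horizons,
                   interval = interval, thresholds = thresholds,
                   learner = lspec$family,
                   n_dev = nrow(dev), n_val = nrow(val),
                   n_cde = nrow(cde),
                   package_version = as.character(utils::packageVersion("picuews"))),
              file.path(out_dir, "manifest.json"))
  invisible(list(cohort = cohort, split = split, events = cde,
                 ensemble = ens, metrics = metrics, curve = curve,
                 burden = burden))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
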