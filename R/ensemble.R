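#' Specify a learner family, hyperparameter grid and cross-validation plan
#'
#' @param family `"gbt"` (gradient-boosted trees, default), `"rf"`
#'   (random forest) or `"lasso"` (L1-regularised logistic regression).
#' @param grid data frame of hyperparameter configurations; defaults to a
#'   deliberately small per-family grid suitable for desk-scale runs.
#' @param cv_folds number of stratified, grouped cross-validation folds
#'   (default 10).
#' @param group_by `"patient"` (default, the stricter leakage guard) or
#'   `"admission"`: the unit that never spans training and held-out folds.
#' @return an object of class `learner_spec`.
#' @export
learner_spec <- function(family = c("gbt", "rf", "lasso"), grid = NULL,
                         cv_folds = 10, group_by = c("patient", "admission")) {
  family <- match.arg(family)
  group_by <- match.arg(group_by)
  if (is.null(grid)) grid <- .default_grid(family)
  structure(list(family = family, grid = grid, cv_folds = cv_folds,
                 group_by = group_by), class = "learner_spec")
}

# Stratified, grouped fold assignment: groups (patients) are labelled
# positive when any of their samples is positive, then positive and
# negative groups are shuffled and dealt round-robin so every fold gets
# both classes and no group spans folds.
.make_folds <- function(y, groups, k, seed) {
  g <- unique(groups)
  g_pos <- unique(groups[y == 1])
  g_neg <- setdiff(g, g_pos)
  .with_seed(seed, {
    g_pos <- sample(g_pos)
    g_neg <- sample(g_neg)
  })
  fold_of <- integer(0)
  assign_rr <- function(ids) if (length(ids))
    stats::setNames(rep_len(seq_len(k), length(ids)), ids) else integer(0)
  fold_of <- c(assign_rr(g_pos), assign_rr(g_neg))
  unname(fold_of[as.character(groups)])
}

#' Train one prediction-horizon model
#'
#' Selects hyperparameters by mean held-out AUROC over stratified,
#' patient-grouped cross-validation folds, then refits the winning
#' configuration on all data.
#'
#' @param x feature matrix (rows = samples, named columns).
#' @param y binary labels.
#' @param horizon the model's horizon in hours (metadata).
#' @param spec a [learner_spec()].
#' @param groups grouping key per row (patient ids); a group never spans
#'   training and held-out folds.
#' @param seed integer seed; the same seed reproduces the same folds,
#'   selection and fit.
#' @param features optional character vector restricting the model to a
#'   feature subset.
#' @param cv set `FALSE` to skip cross-validation (sensible only with a
#'   single-row grid); the model is then fit directly.
#' @return an object of class `horizon_model` with elements `horizon`,
#'   `learner`, `params` and `cv` (per-configuration mean held-out AUROC,
#'   `NULL` when `cv = FALSE`).
#' @export
train_horizon <- function(x, y, horizon, spec = learner_spec(), groups,
                          seed = 1L, features = NULL, cv = TRUE) {
  if (length(unique(y)) < 2)
    .stopf("horizon %s: labels contain a single class", horizon)
  if (!is.null(features)) {
    missing_f <- setdiff(features, colnames(x))
    if (length(missing_f))
      .stopf("unknown feature(s): %s", paste(missing_f, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  k <- spec$cv_folds
  n_groups_min <- min(length(unique(groups[y == 1])),
                      length(unique(groups[y == 0])))
  if (cv && n_groups_min < k) {
    k <- max(2L, n_groups_min)
    .warnf("fewer groups than folds; reducing to %d folds", k)
  }
  grid <- spec$grid
  cv_report <- NULL
  best <- 1L
  if (cv && nrow(grid) >= 1) {
    folds <- .make_folds(y, groups, k, .derive_seed(seed, horizon, "folds"))
    mean_auc <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      aucs <- numeric(k)
      for (f in seq_len(k)) {
        tr <- folds != f
        if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) {
          aucs[f] <- NA
          next
        }
        m <- .fit_learner(spec$family, x[tr, , drop = FALSE], y[tr],
                          as.list(grid[gi, , drop = FALSE]),
                          .derive_seed(seed, horizon, paste0("cv", f)))
        aucs[f] <- auroc(.predict_learner(m, x[!tr, , drop = FALSE]), y[!tr])
      }
      mean_auc[gi] <- mean(aucs, na.rm = TRUE)
    }
    best <- which.max(mean_auc)
    cv_report <- cbind(grid, mean_cv_auroc = mean_auc)
  }
  params <- as.list(grid[best, , drop = FALSE])
  learner <- .fit_learner(spec$family, x, y, params,
                          .derive_seed(seed, horizon, "final"))
  structure(list(horizon = horizon, learner = learner, params = params,
                 features = colnames(x), cv = cv_report),
            class = "horizon_model")
}

#' Train the multi-horizon risk ensemble
#'
#' Trains one classifier per prediction horizon.  The horizon-`h` training
#' set is the union of that horizon's positive snapshots and all control
#' snapshots (controls are shared across horizons).  The fitted ensemble
#' averages the six member probabilities into a single risk index.
#'
#' @param samples sample table from [build_training_samples()], row-aligned
#'   with `x`.
#' @param x feature matrix for `samples` (from [build_matrix()]).
#' @param admissions admission table supplying `patient_id` for fold
#'   grouping.
#' @param spec a [learner_spec()].
#' @param horizons horizons to train (default the distinct non-`NA`
#'   horizons present in `samples`).
#' @param seed integer seed.
#' @param features `NULL`, a character vector applied to every member, or a
#'   named list (names = horizons) of per-member subsets as produced by
#'   [select_parsimonious()].
#' @inheritParams train_horizon
#' @return an object of class `ews_ensemble`.
#' @export
train_ensemble <- function(samples, x, admissions, spec = learner_spec(),
                           horizons = NULL, seed = 1L, features = NULL,
                           cv = TRUE) {
  if (is.null(horizons))
    horizons <- sort(unique(samples$horizon[!is.na(samples$horizon)]))
  groups_all <- admissions$patient_id[match(samples$admission_id,
                                            admissions$admission_id)]
  if (spec$group_by == "admission") groups_all <- samples$admission_id
  members <- list()
  for (h in horizons) {
    sel <- (is.na(samples$horizon) & samples$label == 0) |
      (!is.na(samples$horizon) & samples$horizon == h & samples$label == 1)
    f_h <- if (is.list(features)) features[[as.character(h)]] else features
    members[[as.character(h)]] <- train_horizon(
      x[sel, , drop = FALSE], samples$label[sel], h, spec,
      groups = groups_all[sel], seed = .derive_seed(seed, h, "horizon"),
      features = f_h, cv = cv)
  }
  structure(list(members = members, horizons = horizons,
                 family = spec$family, feature_names = colnames(x)),
            class = "ews_ensemble")
}

#' @export
print.ews_ensemble <- function(x, ...) {
  cat("Multi-horizon risk ensemble (", x$family, "): horizons ",
      paste(x$horizons, collapse = ", "), " h; ",
      length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' Predict the ensemble risk index
#'
#' The risk index is the arithmetic mean of the member (per-horizon)
#' probabilities, so it is invariant to member ordering and lies in
#' `[0, 1]`.
#'
#' @param ensemble an [train_ensemble()] fit.
#' @param x feature matrix with the training column schema.
#' @param per_horizon return the member probability matrix instead of the
#'   mean.
#' @return numeric vector of probabilities (or a matrix with one column per
#'   horizon when `per_horizon = TRUE`).
#' @export
predict_ensemble <- function(ensemble, x, per_horizon = FALSE) {
  if (!identical(colnames(x), ensemble$feature_names))
    .stopf("feature schema mismatch: matrix columns do not match the ensemble's training schema")
  p <- vapply(ensemble$members, function(m)
    .predict_learner(m$learner, x[, m$features, drop = FALSE]),
    numeric(nrow(x)))
  if (nrow(x) == 1) p <- matrix(p, nrow = 1,
                                dimnames = list(NULL, names(ensemble$members)))
  if (per_horizon) p else rowMeans(p)
}

#' Plug-in mutual information between a feature and a binary label
#'
#' Continuous features are discretised into equal-frequency bins (default
#' 10); missing values form their own bin, mirroring how tree learners see
#' missingness.  Returns the maximum-likelihood (plug-in) mutual
#' information in bits.
#'
#' @param feature numeric vector (may contain `NA`).
#' @param y binary labels.
#' @param bins number of equal-frequency bins (default 10).
#' @return mutual information in bits.
#' @export
mutual_information <- function(feature, y, bins = 10) {
  obs <- !is.na(feature)
  b <- rep("NA", length(feature))
  if (any(obs)) {
    distinct <- unique(feature[obs])
    if (length(distinct) <= bins) {
      # few distinct values (discrete/indicator features): use them directly
      b[obs] <- as.character(match(feature[obs], distinct))
    } else {
      qs <- unique(stats::quantile(feature[obs],
                                   probs = seq(0, 1, length.out = bins + 1),
                                   type = 1, names = FALSE))
      b[obs] <- as.character(cut(feature[obs], breaks = qs,
                                 include.lowest = TRUE, labels = FALSE))
    }
  }
  tab <- table(b, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  max(0, mi)
}

#' Select top-k features per horizon by mutual information
#'
#' Ranks every feature by its plug-in mutual information with the label on
#' each horizon's training set (that horizon's positives plus the shared
#' controls) and keeps the top `k` per horizon.  The union across horizons
#' is the parsimonious feature dictionary; retraining the ensemble with
#' `features = ` the per-horizon lists gives the parsimonious model.
#'
#' @inheritParams train_ensemble
#' @param k number of features kept per horizon; if `k` exceeds the feature
#'   count, all features are used with a warning.
#' @param bins passed to [mutual_information()].
#' @return list with `per_horizon` (named list of character vectors, one
#'   per horizon) and `union` (character vector of unique names; length in
#'   `[k, 6k]` for six horizons).
#' @export
select_parsimonious <- function(samples, x, k, horizons = NULL, bins = 10) {
  stopifnot(k >= 1)
  if (is.null(horizons))
    horizons <- sort(unique(samples$horizon[!is.na(samples$horizon)]))
  if (k > ncol(x)) {
    .warnf("k = %d exceeds the %d available features; using all", k, ncol(x))
    k <- ncol(x)
  }
  per <- list()
  for (h in horizons) {
    sel <- (is.na(samples$horizon) & samples$label == 0) |
      (!is.na(samples$horizon) & samples$horizon == h & samples$label == 1)
    mi <- vapply(seq_len(ncol(x)),
                 function(j) mutual_information(x[sel, j], samples$label[sel],
                                                bins = bins),
                 numeric(1))
    per[[as.character(h)]] <- colnames(x)[order(-mi)[seq_len(k)]]
  }
  list(per_horizon = per, union = unique(unlist(per, use.names = FALSE)))
}
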