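# Plug-in learner families behind a common fit/predict-probability
# contract. Gradient-boosted trees (xgboost) consume NA natively; random
# forest and lasso get training-median imputation baked into the fitted
# object.

.default_grid <- function(family) {
  switch(family,
    gbt = expand.grid(max_depth = c(3, 5), eta = 0.1, nrounds = 100,
                      min_child_weight = 1),
    rf = expand.grid(num.trees = 300, mtry_frac = c(0.3, 0.6)),
    lasso = expand.grid(lambda = 10^seq(-1, -4, length.out = 8)),
    .stopf("unknown learner family '%s'", family)
  )
}

.impute_medians <- function(x) {
  apply(x, 2, function(col) {
    m <- stats::median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
}

.apply_impute <- function(x, med) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  x
}

.fit_learner <- function(family, x, y, params, seed) {
  fit <- switch(family,
    gbt = {
      dtr <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      min_child_weight = params$min_child_weight,
                      nthread = 1, seed = seed),
        data = dtr, nrounds = params$nrounds, verbose = 0)
    },
    rf = {
      if (!requireNamespace("ranger", quietly = TRUE))
        .stopf("the random-forest learner family requires the 'ranger' package")
      med <- .impute_medians(x)
      xi <- .apply_impute(x, med)
      df <- as.data.frame(xi)
      df$.y <- factor(y, levels = c(0, 1))
      m <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = params$num.trees,
                          mtry = max(1, floor(params$mtry_frac * ncol(x))),
                          probability = TRUE, num.threads = 1, seed = seed)
      list(model = m, medians = med)
    },
    lasso = {
      if (!requireNamespace("glmnet", quietly = TRUE))
        .stopf("the lasso learner family requires the 'glmnet' package")
      med <- .impute_medians(x)
      xi <- .apply_impute(x, med)
      m <- glmnet::glmnet(xi, y, family = "binomial", alpha = 1,
                          lambda = params$lambda)
      list(model = m, medians = med, lambda = params$lambda)
    },
    .stopf("unknown learner family '%s'", family)
  )
  structure(list(family = family, fit = fit, params = params,
                 feature_names = colnames(x)),
            class = "ews_learner")
}

.predict_learner <- function(learner, x) {
  if (!identical(colnames(x), learner$feature_names))
    .stopf("feature schema mismatch: matrix columns do not match the training schema")
  switch(learner$family,
    gbt = {
      p <- stats::predict(learner$fit, xgboost::xgb.DMatrix(x))
      as.numeric(p)
    },
    rf = {
      xi <- .apply_impute(x, learner$fit$medians)
      pr <- stats::predict(learner$fit$model,
                           data = as.data.frame(xi))$predictions
      as.numeric(pr[, "1"])
    },
    lasso = {
      xi <- .apply_impute(x, learner$fit$medians)
      as.numeric(stats::predict(learner$fit$model, xi, type = "response",
                                s = learner$fit$lambda))
    }
  )
}
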