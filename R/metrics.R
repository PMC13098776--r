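#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic divided by `n1 * n0`, with tied
#' scores counted half (mid-rank convention), which keeps [auroc()] and
#' [delong_test()] mutually consistent.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1); both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    .stopf("auroc is undefined with a single class (n1=%d, n0=%d)", n1, n0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision formulation: precision is accumulated at every change
#' point of recall, stepping over descending unique score thresholds (tied
#' scores enter together).
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0) .stopf("auprc is undefined with zero positives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # group tied scores: cumulative counts at each distinct threshold
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last_of_group]
  n_pred <- last_of_group
  prec <- tp / n_pred
  rec <- tp / n1
  d_rec <- diff(c(0, rec))
  sum(prec * d_rec)
}

#' Stratified bootstrap confidence interval for a score metric
#'
#' Resamples positives and negatives independently with replacement,
#' recomputes `metric`, and returns the percentile interval.  Replicates on
#' which the metric is undefined are redrawn (with a note).
#'
#' @param metric function of `(scores, labels)`, e.g. [auroc()] or
#'   [auprc()].
#' @inheritParams auroc
#' @param B number of bootstrap replicates (default 2000).
#' @param seed integer seed; results are reproducible given the seed.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lo, hi)`, with attribute `"replicates"`.
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 2000, seed = 1L,
                         level = 0.95) {
  labels <- as.integer(labels)
  ip <- which(labels == 1); im <- which(labels == 0)
  if (length(ip) == 0 || length(im) == 0)
    .stopf("stratified bootstrap requires both classes")
  stat <- numeric(B)
  redraws <- 0L
  .with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- c(sample(ip, length(ip), replace = TRUE),
                 sample(im, length(im), replace = TRUE))
        v <- tryCatch(metric(scores[idx], labels[idx]), error = function(e) NA)
        if (!is.na(v)) break
        redraws <- redraws + 1L
        if (redraws > 10 * B) .stopf("metric undefined on too many replicates")
      }
      stat[b] <- v
    }
  })
  if (redraws > 0)
    message(sprintf("bootstrap_ci: %d undefined replicate(s) redrawn", redraws))
  a <- (1 - level) / 2
  ci <- stats::quantile(stat, c(a, 1 - a), names = FALSE, type = 7)
  out <- c(lo = ci[1], hi = ci[2])
  attr(out, "replicates") <- stat
  out
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties half), and symmetrically for negatives.
.placements <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  n1 <- length(sp); n0 <- length(sn)
  r_all <- rank(c(sp, sn), ties.method = "average")
  r_pos <- rank(sp, ties.method = "average")
  r_neg <- rank(sn, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0          # per-positive placement
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1 # per-negative placement
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired DeLong test for the difference of two AUROCs
#'
#' Compares two models scored on the *same* samples using the DeLong
#' covariance of the paired placement values; the two-sided p-value comes
#' from the normal approximation.  Zero variance (e.g. identical score
#' vectors) returns `p = 1` by convention.
#'
#' @param scores_a,scores_b paired score vectors of equal length.
#' @inheritParams auroc
#' @return list with `auc_a`, `auc_b`, `delta` (`auc_a - auc_b`), `z`,
#'   `p_value`, and `var_delta`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    .stopf("delong_test requires paired scores of equal length")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) .stopf("delong_test requires both classes")
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  d10 <- pa$v10 - pb$v10
  d01 <- pa$v01 - pb$v01
  var_delta <- stats::var(d10) / n1 + stats::var(d01) / n0
  delta <- pa$auc - pb$auc
  if (!is.finite(var_delta) || var_delta <= 0) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z, p_value = p,
       var_delta = var_delta)
}

# DeLong variance of one AUROC (used for unpaired subgroup comparisons).
.auc_variance <- function(scores, labels) {
  labels <- as.integer(labels)
  p <- .placements(scores, labels)
  stats::var(p$v10) / sum(labels == 1) + stats::var(p$v01) / sum(labels == 0)
}

#' Benjamini-Hochberg adjustment with a rejection set
#'
#' Step-up false-discovery-rate control; q-values are monotone by
#' construction (cumulative minimum from the largest p).
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @param alpha rejection level on the q-values (default 0.05).
#' @return list with `q` (adjusted values, input order) and `reject`
#'   (logical).  Rejections at `q < alpha` are always a subset of raw
#'   `p < alpha` rejections.
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, reject = !is.na(q) & q < alpha)
}

#' Operating points at target sensitivities
#'
#' For each target sensitivity, picks the *largest* threshold (classify
#' positive iff `score >= threshold`) whose sensitivity meets or exceeds
#' the target, and reports sensitivity, specificity, positive predictive
#' value and the sample-level number needed to alert `NNA = 1/PPV`.
#'
#' @inheritParams auroc
#' @param targets sensitivity targets in `[0, 1]`.
#' @return data frame with one row per target.
#' @export
operating_points <- function(scores, labels, targets = c(0.8)) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) .stopf("operating_points requires both classes")
  if (any(targets > 1 | targets < 0)) .stopf("sensitivity targets must be in [0, 1]")
  thr <- sort(unique(scores), decreasing = TRUE)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last_of_group]
  fp <- last_of_group - tp
  sens <- tp / n1
  spec <- 1 - fp / n0
  ppv <- tp / (tp + fp)
  out <- lapply(targets, function(tg) {
    i <- which(sens >= tg)[1]   # thresholds descend, sens ascends
    if (is.na(i)) .stopf("sensitivity target %.2f unreachable", tg)
    data.frame(target = tg, threshold = thr[i], sensitivity = sens[i],
               specificity = spec[i], ppv = ppv[i], nna = 1 / ppv[i])
  })
  do.call(rbind, out)
}

#' Subgroup discrimination (fairness) report
#'
#' Computes per-subgroup AUROC with stratified bootstrap confidence
#' intervals and compares every subgroup against the reference level with
#' an unpaired z-test built from the per-group DeLong variances (subgroups
#' are disjoint samples, so the paired DeLong form does not apply).
#' P-values across all evaluable comparisons are Benjamini-Hochberg
#' adjusted.  Subgroups lacking both classes are flagged not-evaluable and
#' excluded from the testing family.
#'
#' @inheritParams auroc
#' @param group factor/character subgroup tag per sample.
#' @param reference reference level (default: largest evaluable subgroup).
#' @param B,seed bootstrap parameters (see [bootstrap_ci()]).
#' @return data frame with one row per subgroup: `n`, `auroc`, `ci_lo`,
#'   `ci_hi`, `delta_vs_ref`, `z`, `p_value`, `q_value`, `evaluable`.
#' @export
fairness_report <- function(scores, labels, group, reference = NULL,
                            B = 2000, seed = 1L) {
  labels <- as.integer(labels)
  group <- as.character(group)
  levels <- unique(group)
  evaluable <- vapply(levels, function(g) {
    y <- labels[group == g]
    sum(y == 1) > 0 && sum(y == 0) > 0
  }, logical(1))
  if (is.null(reference)) {
    sizes <- vapply(levels, function(g) sum(group == g), numeric(1))
    sizes[!evaluable] <- -1
    reference <- levels[which.max(sizes)]
  }
  if (!evaluable[match(reference, levels)])
    .stopf("reference subgroup '%s' is not evaluable", reference)
  ref_sel <- group == reference
  a_ref <- auroc(scores[ref_sel], labels[ref_sel])
  v_ref <- .auc_variance(scores[ref_sel], labels[ref_sel])
  rows <- lapply(seq_along(levels), function(i) {
    g <- levels[i]
    sel <- group == g
    if (!evaluable[i])
      return(data.frame(group = g, n = sum(sel), auroc = NA, ci_lo = NA,
                        ci_hi = NA, delta_vs_ref = NA, z = NA, p_value = NA,
                        evaluable = FALSE))
    a <- auroc(scores[sel], labels[sel])
    ci <- bootstrap_ci(auroc, scores[sel], labels[sel], B = B,
                       seed = .derive_seed(seed, g, "fair"))
    if (g == reference) {
      d <- 0; z <- NA_real_; p <- NA_real_
    } else {
      v <- .auc_variance(scores[sel], labels[sel])
      d <- a - a_ref
      z <- d / sqrt(v + v_ref)
      p <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(group = g, n = sum(sel), auroc = a, ci_lo = ci[["lo"]],
               ci_hi = ci[["hi"]], delta_vs_ref = d, z = z, p_value = p,
               evaluable = TRUE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  tested <- out$evaluable & !is.na(out$p_value)
  if (any(tested)) out$q_value[tested] <- bh_adjust(out$p_value[tested])$q
  attr(out, "reference") <- reference
  out
}
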