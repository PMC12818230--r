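# Evaluation protocol: stratified splitting, diagnostic metrics, a decision
# threshold matched to the rule comparator's specificity on the tuning set,
# percentile bootstrap CIs (B = 1000) and paired bootstrap differences.

#' Stratified train/tuning/validation split
#'
#' Per-stratum largest-remainder allocation so that each split carries the
#' same outcome proportion (within one patient); assignment within a stratum
#' is a seeded permutation.
#'
#' @param ids vector of patient identifiers.
#' @param strata outcome (or other) stratification vector, same length.
#' @param fractions named split fractions summing to 1
#'   (default train 0.50, tune 0.25, validate 0.25).
#' @param seed integer seed.
#' @return data frame `id`, `stratum`, `split`.
#' @export
stratified_split <- function(ids, strata,
                             fractions = c(train = 0.5, tune = 0.25,
                                           validate = 0.25),
                             seed = 1L) {
  stopifnot(length(ids) == length(strata))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  splits <- names(fractions)
  out <- rep(NA_character_, length(ids))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      m <- length(idx)
      if (m < length(fractions))
        warning("stratum '", s, "' smaller than the number of splits; ",
                "best-effort allocation", call. = FALSE)
      base <- floor(fractions * m)
      rem <- m - sum(base)
      if (rem > 0) {
        frac <- fractions * m - base
        extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      assignment <- rep(splits, times = base)
      out[idx] <- assignment[order(sample.int(m))]
    }
  })
  data.frame(id = ids, stratum = strata, split = out)
}

#' Confusion-matrix metrics for binary predictions
#'
#' @param predictions logical (or 0/1) predicted positives.
#' @param labels logical (or 0/1) true positives.
#' @return named list: `sensitivity`, `specificity`, `ppv`, `npv` (each
#'   `NA` when its denominator is empty) plus the `tp`/`fp`/`tn`/`fn`
#'   counts.
#' @export
confusion_metrics <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length", call. = FALSE)
  p <- as.logical(predictions); y <- as.logical(labels)
  tp <- sum(p & y); fp <- sum(p & !y); tn <- sum(!p & !y); fn <- sum(!p & y)
  rate <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  list(sensitivity = rate(tp, fn), specificity = rate(tn, fp),
       ppv = rate(tp, fp), npv = rate(tn, fn),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Area under the ROC curve
#'
#' Midrank Mann-Whitney estimator: the probability that a random positive
#' scores above a random negative, ties counted half.
#'
#' @param scores numeric risk scores.
#' @param labels logical (or 0/1) outcome.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Match the model threshold to a comparator's specificity
#'
#' Target specificity is taken from the comparator's verdicts on the tuning
#' set; the returned threshold is the smallest score cut-off whose tuning
#' specificity is at least the target (an exact match is generally
#' unattainable on finite data).
#'
#' @param scores tuning-set risk scores.
#' @param labels tuning-set outcomes (logical).
#' @param target_specificity fraction in `[0, 1]`, e.g. the comparator's
#'   tuning specificity.
#' @return list `threshold`, `achieved_specificity`, `target_specificity`.
#' @export
match_specificity_threshold <- function(scores, labels, target_specificity) {
  y <- as.logical(labels)
  neg <- sort(scores[!y])
  if (!length(neg)) stop("no negatives in tuning data", call. = FALSE)
  cand <- sort(unique(c(scores, max(scores) + 1)))
  spec_at <- vapply(cand, function(th) mean(neg < th), 0)
  # specificity at threshold th = P(negative score < th); want smallest th
  # with spec >= target
  ok <- which(spec_at >= target_specificity)
  th <- cand[ok[1]]
  list(threshold = th, achieved_specificity = spec_at[ok[1]],
       target_specificity = target_specificity)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples patients with replacement; resamples on which the metric is
#' undefined (empty denominator, single class) are skipped and counted.
#'
#' @param metric_fn function(indices) -> scalar metric, evaluated on a
#'   resample given by integer indices into the data.
#' @param n number of patients to resample from.
#' @param n_bootstrap number of resamples B (default 1000).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list `lo`, `hi`, `n_skipped`, `replicates`.
#' @export
bootstrap_ci <- function(metric_fn, n, n_bootstrap = 1000, ci_level = 0.95,
                         seed = 1L) {
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1", call. = FALSE)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  reps <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(as.numeric(metric_fn(idx)), error = function(e) NA_real_)
    }, 0)
  })
  ok <- reps[!is.na(reps)]
  alpha <- (1 - ci_level) / 2
  q <- quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lo = q[1], hi = q[2], n_skipped = sum(is.na(reps)), replicates = reps)
}

#' Paired bootstrap difference between two models
#'
#' Both metrics are computed on the same resample of the same patients; the
#' CI is the percentile interval of the per-resample difference (a - b).
#'
#' @param metric_fn_a,metric_fn_b functions(indices) -> scalar metric for the
#'   two models, over identical patients.
#' @param n number of patients.
#' @param n_bootstrap,ci_level,seed as in [bootstrap_ci()].
#' @return list `point` (full-sample difference), `lo`, `hi`, `n_skipped`.
#' @export
bootstrap_difference <- function(metric_fn_a, metric_fn_b, n,
                                 n_bootstrap = 1000, ci_level = 0.95,
                                 seed = 1L) {
  ci <- bootstrap_ci(function(idx) metric_fn_a(idx) - metric_fn_b(idx),
                     n, n_bootstrap, ci_level, seed)
  full <- seq_len(n)
  list(point = metric_fn_a(full) - metric_fn_b(full),
       lo = ci$lo, hi = ci$hi, n_skipped = ci$n_skipped)
}

#' Diagnostic metrics with bootstrap CIs for one model/cohort/threshold
#'
#' @param scores risk scores (or binary verdicts coerced to 0/1 for a rule
#'   comparator, in which case `auc` is omitted).
#' @param labels outcomes (logical).
#' @param threshold decision threshold applied to `scores`.
#' @param n_bootstrap,ci_level,seed bootstrap settings.
#' @param binary set `TRUE` for a rule comparator: no AUC is reported.
#' @param cohort descriptor string.
#' @return a `metrics_report` list with point estimates and CIs for
#'   sensitivity, specificity, ppv, npv (and auc unless `binary`).
#' @export
metrics_report <- function(scores, labels, threshold, n_bootstrap = 1000,
                           ci_level = 0.95, seed = 1L, binary = FALSE,
                           cohort = "validation") {
  y <- as.logical(labels)
  pred <- scores >= threshold
  cm <- confusion_metrics(pred, y)
  mk <- function(name) {
    fn <- function(idx) confusion_metrics(pred[idx], y[idx])[[name]]
    ci <- bootstrap_ci(function(idx) {
      v <- fn(idx); if (is.na(v)) stop("undefined") else v
    }, length(y), n_bootstrap, ci_level, seed)
    c(point = cm[[name]], lo = ci$lo, hi = ci$hi)
  }
  out <- list(sensitivity = mk("sensitivity"), specificity = mk("specificity"),
              ppv = mk("ppv"), npv = mk("npv"))
  if (!binary && length(unique(y)) > 1) {
    aci <- bootstrap_ci(function(idx) roc_auc(scores[idx], y[idx]),
                        length(y), n_bootstrap, ci_level, seed)
    out$auc <- c(point = roc_auc(scores, y), lo = aci$lo, hi = aci$hi)
  }
  structure(c(out, list(threshold = threshold, n = length(y),
                        cohort = cohort)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s (n=%d, threshold=%.4g)\n",
              x$cohort, x$n, x$threshold))
  for (m in c("auc", "sensitivity", "specificity", "ppv", "npv")) {
    if (is.null(x[[m]])) next
    v <- x[[m]]
    cat(sprintf("  %-12s %.3f (%.3f-%.3f)\n", m, v["point"], v["lo"], v["hi"]))
  }
  invisible(x)
}

#' Subgroup evaluation at the global threshold
#'
#' Metrics are recomputed on the filtered cohort; thresholds are never
#' re-fitted per subgroup.
#'
#' @param scores,labels full-cohort scores and outcomes.
#' @param subgroups named list of logical filters over the cohort.
#' @param threshold global decision threshold.
#' @param ... passed to [metrics_report()].
#' @return named list of `metrics_report` (absent entries for empty
#'   subgroups).
#' @export
subgroup_eval <- function(scores, labels, subgroups, threshold, ...) {
  out <- list()
  for (nm in names(subgroups)) {
    sel <- subgroups[[nm]]
    if (!any(sel)) next
    if (length(unique(as.logical(labels[sel]))) < 2) next  # degenerate
    out[[nm]] <- metrics_report(scores[sel], labels[sel], threshold,
                                cohort = nm, ...)
  }
  out
}
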