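test_that("stratified splitting allocates by largest remainder within strata", {
  n <- 24511; n_omi <- 467
  strata <- c(rep("OMI", n_omi), rep("neg", n - n_omi))
  sp <- stratified_split(sprintf("P%05d", 1:n), strata, seed = 5)
  sizes <- table(sp$split)
  # independent largest-remainder oracle, per stratum then summed
  alloc <- function(m, f = c(train = 0.5, tune = 0.25, validate = 0.25)) {
    base <- floor(f * m); rem <- m - sum(base)
    frac <- f * m - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
    base
  }
  expected <- alloc(n_omi) + alloc(n - n_omi)
  expect_equal(as.numeric(sizes[names(expected)]), as.numeric(expected))
  expect_equal(sum(sizes), n)

  # outcome proportion preserved within one patient
  for (s in c("train", "tune", "validate")) {
    k <- sum(sp$stratum == "OMI" & sp$split == s)
    expect_lt(abs(k - sum(sp$split == s) * n_omi / n), 1.5)
  }
  sp2 <- stratified_split(sprintf("P%05d", 1:n), strata, seed = 5)
  expect_identical(sp, sp2)
  expect_warning(stratified_split(c("a", "b"), c("x", "x")), "smaller")
  expect_error(stratified_split("a", "x", fractions = c(a = 0.6, b = 0.6)),
               "sum to 1")
})

test_that("confusion metrics reproduce hand-computed tables", {
  # a rule flagging 107 of 467 positives: sensitivity 22.9%
  y <- c(rep(TRUE, 467), rep(FALSE, 1000))
  p <- c(rep(TRUE, 107), rep(FALSE, 360), rep(FALSE, 1000))
  cm <- confusion_metrics(p, y)
  expect_equal(cm$sensitivity, 107 / 467)
  expect_equal(pct_of(cm$tp, cm$tp + cm$fn), 22.9)

  all_right <- confusion_metrics(y, y)
  expect_equal(unlist(all_right[c("sensitivity", "specificity", "ppv",
                                  "npv")]), c(sensitivity = 1,
                                              specificity = 1, ppv = 1,
                                              npv = 1))
  none <- confusion_metrics(rep(FALSE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(is.na(none$ppv))
  expect_equal(none$sensitivity, 0)
  expect_error(confusion_metrics(c(TRUE), c(TRUE, FALSE)), "length")
})

test_that("AUC equals brute-force pair counting, with ties counted half", {
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(scores, labels), auc_bruteforce(scores, labels))

  set.seed(9)
  s2 <- sample(seq(0, 1, by = 0.05), 300, replace = TRUE)  # heavy ties
  y2 <- runif(300) < 0.4
  expect_equal(roc_auc(s2, y2), auc_bruteforce(s2, y2))

  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # independent library route agrees
  expect_equal(roc_auc(s2, y2),
               as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE,
                                              direction = "<"))))
  set.seed(10)
  expect_lt(abs(roc_auc(rnorm(10000), runif(10000) < 0.5) - 0.5), 0.02)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("matched-specificity thresholds agree with an exhaustive scan", {
  set.seed(11)
  scores <- round(runif(40), 2)
  labels <- c(rep(TRUE, 10), rep(FALSE, 30))
  for (target in c(0.5, 0.8, 0.9)) {
    got <- match_specificity_threshold(scores, labels, target)
    neg <- scores[!labels]
    cand <- sort(unique(c(scores, max(scores) + 1)))
    ok <- cand[vapply(cand, function(th) mean(neg < th) >= target, TRUE)]
    expect_equal(got$threshold, min(ok))
    expect_gte(got$achieved_specificity, target)
  }
  # a perfectly specific comparator forces the threshold above every negative
  got1 <- match_specificity_threshold(scores, labels, 1.0)
  expect_gt(got1$threshold, max(scores[!labels]))
  # monotone in the target
  th <- vapply(c(0.2, 0.5, 0.8, 0.95, 1), function(t)
    match_specificity_threshold(scores, labels, t)$threshold, 0)
  expect_true(all(diff(th) >= 0))
  expect_error(match_specificity_threshold(scores[labels], labels[labels],
                                           0.9), "no negatives")
})

test_that("bootstrap intervals are seeded, and degenerate metrics give zero width", {
  y <- rep(TRUE, 50)
  ci <- bootstrap_ci(function(idx) mean(y[idx]), 50, n_bootstrap = 200,
                     seed = 3)
  expect_equal(ci$lo, 1); expect_equal(ci$hi, 1)
  set.seed(12)
  x <- rnorm(80)
  c1 <- bootstrap_ci(function(idx) mean(x[idx]), 80, seed = 4)
  c2 <- bootstrap_ci(function(idx) mean(x[idx]), 80, seed = 4)
  expect_identical(c1, c2)
  expect_error(bootstrap_ci(mean, 80, n_bootstrap = 0), "n_bootstrap")
  expect_error(bootstrap_ci(mean, 1), "at least 2")
})

test_that("paired bootstrap differences behave definitionally", {
  set.seed(13)
  y <- runif(300) < 0.3
  good <- ifelse(y, runif(300) < 0.9, runif(300) < 0.05)
  weak <- ifelse(y, runif(300) < 0.4, runif(300) < 0.05)
  sens <- function(p) function(idx) {
    cm <- confusion_metrics(p[idx], y[idx])
    if (is.na(cm$sensitivity)) stop("undefined")
    cm$sensitivity
  }
  self <- bootstrap_difference(sens(good), sens(good), 300, seed = 5)
  expect_equal(self$point, 0); expect_equal(self$lo, 0); expect_equal(self$hi, 0)

  d <- bootstrap_difference(sens(good), sens(weak), 300, seed = 5)
  expect_equal(d$point,
               confusion_metrics(good, y)$sensitivity -
                 confusion_metrics(weak, y)$sensitivity)
  expect_gt(d$lo, 0)  # strict dominance: the CI excludes zero
})

test_that("subgroup evaluation partitions counts and keeps the global threshold", {
  set.seed(14)
  y <- runif(400) < 0.25
  sc <- ifelse(y, rnorm(400, 1.2), rnorm(400))
  sex <- sample(c("female", "male"), 400, replace = TRUE)
  thr <- 0.8
  whole <- confusion_metrics(sc >= thr, y)
  parts <- subgroup_eval(sc, y, list(female = sex == "female",
                                     male = sex == "male"),
                         thr, n_bootstrap = 20, seed = 2)
  expect_equal(parts$female$threshold, thr)
  tp_sum <- sum(vapply(parts, function(r)
    round(r$sensitivity[["point"]] * sum(y[sex == r$cohort])), 0))
  expect_equal(tp_sum, whole$tp)
  empty <- subgroup_eval(sc, y, list(none = rep(FALSE, 400)), thr)
  expect_length(empty, 0)
})

test_that("metric reports carry ordered point estimates and intervals", {
  set.seed(15)
  y <- runif(500) < 0.2
  sc <- ifelse(y, rnorm(500, 1.5), rnorm(500))
  r <- metrics_report(sc, y, 1.0, n_bootstrap = 100, seed = 6)
  for (m in c("auc", "sensitivity", "specificity", "ppv", "npv")) {
    v <- r[[m]]
    expect_lte(v[["lo"]], v[["point"]] + 1e-9)
    expect_gte(v[["hi"]], v[["point"]] - 1e-9)
    expect_true(all(v >= 0 & v <= 1))
  }
  rb <- metrics_report(as.numeric(y), y, 0.5, n_bootstrap = 20, seed = 6,
                       binary = TRUE)
  expect_null(rb$auc)
})
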