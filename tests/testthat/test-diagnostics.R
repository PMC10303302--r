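test_that("confusion tabulation at a cutoff matches per-record counting", {
  co <- random_cohort(40, seed = 5)
  # perfect agreement: no false calls
  perfect <- paired_cohort(co$vessel_id, co$invasive_ffr, co$invasive_ffr)
  cm <- confusion_at_cutoff(perfect, 0.80)
  expect_equal(cm$fp, 0L)
  expect_equal(cm$fn, 0L)

  # cutoff 0: nothing called positive
  cm0 <- confusion_at_cutoff(co, 0)
  expect_equal(cm0$tp + cm0$fp, 0L)

  # random cohort vs brute-force tabulation
  for (cut in c(0.7, 0.8, 0.9)) {
    cm <- confusion_at_cutoff(co, cut)
    pred <- co$index_value <= cut
    truth <- co$invasive_ffr <= 0.80
    expect_equal(cm$tp, sum(pred & truth))
    expect_equal(cm$fp, sum(pred & !truth))
    expect_equal(cm$tn, sum(!pred & !truth))
    expect_equal(cm$fn, sum(!pred & truth))
  }
})

test_that("Clopper-Pearson intervals are exact beta quantiles", {
  # boundary behaviour
  expect_equal(clopper_pearson(0, 10)[["lo"]], 0)
  expect_equal(clopper_pearson(10, 10)[["hi"]], 1)

  # agreement with stats::binom.test across counts
  for (x in c(0, 1, 6, 17, 28, 34, 36)) {
    got <- clopper_pearson(x, 36)
    ref <- binom.test(x, 36)$conf.int
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-10)
  }
  expect_error(clopper_pearson(5, 4), "successes <= trials")
})

test_that("index panel identities hold for arbitrary confusion matrices", {
  set.seed(21)
  for (k in 1:25) {
    cts <- rmultinom(1, 40, c(0.45, 0.1, 0.3, 0.15))[, 1]
    if (any(cts == 0)) next
    cm <- confusion_matrix(cts[1], cts[2], cts[3], cts[4])
    di <- diagnostic_indices(cm)
    N <- cm$tp + cm$fp + cm$tn + cm$fn
    expect_equal(di$accuracy_pct / 100 * N, cm$tp + cm$tn, tolerance = 1e-9)
    expect_equal(di$youden,
                 di$sensitivity_pct / 100 + di$specificity_pct / 100 - 1,
                 tolerance = 1e-12)
    sens <- cm$tp / (cm$tp + cm$fn); spec <- cm$tn / (cm$tn + cm$fp)
    expect_equal(di$plr, sens / (1 - spec), tolerance = 1e-12)
    expect_equal(di$nlr, (1 - sens) / spec, tolerance = 1e-12)
    expect_equal(di$false_discovery_rate_pct, 100 - di$ppv_pct, tolerance = 1e-9)
    expect_equal(di$false_omission_rate_pct, 100 - di$npv_pct, tolerance = 1e-9)
    # every CI contains its point estimate
    expect_true(di$accuracy_ci_pct[1] <= di$accuracy_pct &&
                  di$accuracy_pct <= di$accuracy_ci_pct[2])
    expect_true(di$plr_ci[1] <= di$plr && di$plr <= di$plr_ci[2])
    expect_true(di$nlr_ci[1] <= di$nlr && di$nlr <= di$nlr_ci[2])
  }

  # perfect classifier
  di <- diagnostic_indices(confusion_matrix(10, 0, 10, 0))
  expect_equal(di$sensitivity_pct, 100)
  expect_equal(di$specificity_pct, 100)
  expect_equal(di$youden, 1)
  # undefined indices are NA, not fabricated
  di0 <- diagnostic_indices(confusion_matrix(0, 0, 5, 5))
  expect_true(is.na(di0$ppv_pct))
})

test_that("AUC equals exhaustive concordant-pair counting and pROC", {
  # perfectly separated cohort
  co <- paired_cohort(1:10, c(rep(0.6, 5), rep(0.9, 5)),
                      c(rep(0.7, 5), rep(0.9, 5)))
  expect_equal(roc_analysis(co)$auc, 1.0)

  # pure ties
  co_t <- paired_cohort(1:10, rep(0.8, 10), c(rep(0.7, 5), rep(0.9, 5)))
  expect_equal(roc_analysis(co_t)$auc, 0.5)

  # hand-built 12-record cohort vs O(n^2) pair oracle
  co12 <- paired_cohort(1:12,
                        c(0.62, 0.71, 0.74, 0.74, 0.78, 0.80, 0.80, 0.82,
                          0.85, 0.88, 0.74, 0.91),
                        c(0.60, 0.70, 0.75, 0.79, 0.80, 0.80, 0.83, 0.86,
                          0.88, 0.90, 0.72, 0.95))
  pair_auc <- function(co) {
    pos <- co$index_value[co$invasive_ffr <= 0.80]
    neg <- co$index_value[co$invasive_ffr > 0.80]
    s <- 0
    for (p in pos) for (q in neg) s <- s + (p < q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
  }
  expect_equal(roc_analysis(co12)$auc, pair_auc(co12), tolerance = 1e-12)

  # independent cross-check against pROC on random cohorts
  for (seed in c(2, 9)) {
    co <- random_cohort(30, seed)
    got <- roc_analysis(co)$auc
    ref <- suppressMessages(pROC::auc(
      factor(co$invasive_ffr <= 0.80), co$index_value,
      direction = ">", quiet = TRUE))
    expect_equal(got, as.numeric(ref), tolerance = 1e-10)
  }

  expect_error(roc_analysis(paired_cohort(1:4, c(.7, .7, .8, .9),
                                          rep(0.7, 4))),
               "positive and.*negative")
})

test_that("threshold-sweep trapezoid AUC equals the Mann-Whitney statistic", {
  for (seed in 1:200) {
    co <- random_cohort(sample(6:50, 1), seed)
    roc <- roc_analysis(co)
    expect_equal(trapezoid_auc(roc), roc$auc, tolerance = 1e-10)
  }
})

test_that("optimal cutoff maximizes Youden with ties broken toward 0.80", {
  co <- paired_cohort(1:8, c(0.70, 0.72, 0.75, 0.78, 0.85, 0.88, 0.90, 0.93),
                      c(0.70, 0.74, 0.76, 0.79, 0.85, 0.87, 0.91, 0.94))
  roc <- roc_analysis(co)
  # perfect separation: many cutoffs achieve Youden 1; nearest to 0.80 wins
  expect_equal(roc$optimal_youden, 1)
  expect_equal(roc$optimal_cutoff, 0.80)
  expect_equal(roc$optimal_sens, 1)
  expect_equal(roc$optimal_spec, 1)
})

test_that("correlation and Bland-Altman agree with direct formulas", {
  x <- c(0.62, 0.68, 0.71, 0.75, 0.78, 0.81, 0.84, 0.86, 0.90, 0.93)
  expect_equal(paired_correlation(x, x)$r, 1)
  expect_equal(paired_correlation(x, 2 - x)$r, -1, tolerance = 1e-12)

  set.seed(4)
  y <- x + rnorm(10, sd = 0.05)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(paired_correlation(x, y)$r, r_manual, tolerance = 1e-12)
  expect_equal(paired_correlation(x, y, "spearman")$r,
               cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(paired_correlation(x, rep(1, 10)), "variance")

  ba <- bland_altman(x, x)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_low, 0)
  ba2 <- bland_altman(x, x + 0.05)
  expect_equal(ba2$mean_diff, -0.05)
  expect_equal(ba2$sd_diff, 0)
  d <- x - y
  ba3 <- bland_altman(x, y)
  expect_equal(ba3$mean_diff, mean(d))
  expect_equal(ba3$sd_diff, sd(d))
  expect_equal(ba3$loa_high, mean(d) + 1.96 * sd(d))
  expect_error(bland_altman(x, y[1:5]), "equal length")
})

test_that("two-method comparison composes the underlying statistics", {
  pair <- engineered_cohort_pair(seed = 3)
  cmp <- compare_methods(pair$ivus, pair$ct, labels = c("ivus", "ct"))

  # identical cohorts give identical columns
  cmp_same <- compare_methods(pair$ivus, pair$ivus)
  expect_equal(tidy(cmp_same$indices_a), tidy(cmp_same$indices_b))

  # cells recomputed by calling the operations independently
  expect_equal(cmp$indices_a$accuracy_pct,
               diagnostic_indices(confusion_at_cutoff(pair$ivus, 0.80))$accuracy_pct)
  expect_equal(cmp$roc_b$auc, roc_analysis(pair$ct)$auc)
  expect_equal(cmp$ba_a$mean_diff,
               mean(pair$ivus$index_value - pair$ivus$invasive_ffr))
  expect_equal(cmp$cor_ab$r,
               paired_correlation(pair$ivus$index_value, pair$ct$index_value)$r)

  # mismatched ids are rejected
  other <- paired_cohort(sprintf("X%02d", 1:36), pair$ct$index_value,
                         pair$ct$invasive_ffr)
  expect_error(compare_methods(pair$ivus, other), "same vessel ids")
})
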