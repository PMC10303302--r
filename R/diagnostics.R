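#' Build a paired cohort of index vs invasive FFR measurements
#'
#' One record per vessel: a computed index value (e.g. an image-derived FFR
#' estimate) paired with the invasive wire FFR. Disease positivity is defined
#' on the invasive side as FFR <= 0.80 (hemodynamically significant
#' stenosis).
#'
#' @param vessel_id Vessel identifiers (unique).
#' @param index_value Index measurements in (0, 1].
#' @param invasive_ffr Invasive FFR in (0, 1].
#' @return A tibble of class `paired_cohort`.
#' @export
paired_cohort <- function(vessel_id, index_value, invasive_ffr) {
  n <- length(vessel_id)
  if (length(index_value) != n || length(invasive_ffr) != n) {
    abort("All cohort columns must have the same length.")
  }
  if (n < 2L) abort("A cohort needs at least 2 vessels.")
  if (anyNA(index_value) || anyNA(invasive_ffr)) abort("Cohort values must be non-missing.")
  if (any(index_value <= 0 | index_value > 1) || any(invasive_ffr <= 0 | invasive_ffr > 1)) {
    abort("Index and invasive FFR values must lie in (0, 1].")
  }
  if (anyDuplicated(vessel_id)) abort("`vessel_id` must be unique.")
  out <- tibble(vessel_id = vessel_id,
                index_value = as.numeric(index_value),
                invasive_ffr = as.numeric(invasive_ffr))
  class(out) <- c("paired_cohort", class(out))
  out
}

#' @rdname paired_cohort
#' @param data Data frame with columns `vessel_id`, `index_value`,
#'   `invasive_ffr`.
#' @export
as_paired_cohort <- function(data) {
  if (inherits(data, "paired_cohort")) return(data)
  need <- c("vessel_id", "index_value", "invasive_ffr")
  if (!all(need %in% names(data))) {
    abort(paste0("Missing column(s): ",
                 paste(setdiff(need, names(data)), collapse = ", ")))
  }
  paired_cohort(data$vessel_id, data$index_value, data$invasive_ffr)
}

#' Confusion matrix of counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.")
  }
  if (sum(counts) < 1) abort("At least one observation is required.")
  counts <- setNames(as.integer(counts), names(counts))
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Cross-tabulate an index against invasive FFR at a cutoff
#'
#' Predicted positive when `index_value <= cutoff`; truly positive when
#' `invasive_ffr <= ffr_threshold` (0.80, the significance threshold).
#'
#' @param cohort A [paired_cohort()].
#' @param cutoff Index cutoff.
#' @param ffr_threshold Invasive positivity threshold (default 0.80).
#' @return A [confusion_matrix()].
#' @export
confusion_at_cutoff <- function(cohort, cutoff, ffr_threshold = 0.80) {
  cohort <- as_paired_cohort(cohort)
  pred <- cohort$index_value <= cutoff
  truth <- cohort$invasive_ffr <= ffr_threshold
  confusion_matrix(
    tp = sum(pred & truth), fp = sum(pred & !truth),
    tn = sum(!pred & !truth), fn = sum(!pred & truth)
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile interval: `lo = qbeta(a/2, x, n - x + 1)`,
#' `hi = qbeta(1 - a/2, x + 1, n - x)`, with `lo = 0` when `x = 0` and
#' `hi = 1` when `x = n`.
#'
#' @param successes,trials Counts, `0 <= successes <= trials`, `trials >= 1`.
#' @param level Confidence level, default 0.95.
#' @return Named numeric `c(lo, hi)` on the proportion scale.
#' @export
#' @examples
#' clopper_pearson(34, 36)  # 0.813 - 0.993
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials)) {
    abort("Need integer counts with 0 <= successes <= trials and trials >= 1.")
  }
  a <- 1 - level
  lo <- if (successes == 0) 0 else qbeta(a / 2, successes, trials - successes + 1)
  hi <- if (successes == trials) 1 else qbeta(1 - a / 2, successes + 1, trials - successes)
  c(lo = lo, hi = hi)
}

# standard-logit (Mercaldo) interval for a predictive value; est on (0,1)
logit_ci <- function(est, var_logit, z) {
  if (!is.finite(var_logit) || est <= 0 || est >= 1) return(c(lo = NA_real_, hi = NA_real_))
  lg <- log(est / (1 - est))
  lo <- lg - z * sqrt(var_logit)
  hi <- lg + z * sqrt(var_logit)
  c(lo = 1 / (1 + exp(-lo)), hi = 1 / (1 + exp(-hi)))
}

#' Full diagnostic-index panel from a confusion matrix
#'
#' Point estimates and 95% CIs for accuracy, sensitivity, specificity, PPV,
#' NPV, positive and negative likelihood ratios, plus the Youden index
#' (`sens/100 + spec/100 - 1`, on fractions), false discovery and false
#' omission rates, and the misclassification percentage. CI families:
#' exact Clopper-Pearson for accuracy/sensitivity/specificity,
#' standard-logit (Mercaldo) intervals for PPV/NPV, and the Simel log method
#' for likelihood ratios. Indices with zero denominators are returned as
#' `NA`, never fabricated.
#'
#' @param cm A [confusion_matrix()].
#' @param ci_level Confidence level, default 0.95.
#' @return An object of class `diagnostic_indices`; see [tidy()] for a
#'   tabular view. Percent-scale statistics are in percent; likelihood
#'   ratios and Youden are unitless.
#' @export
#' @examples
#' diagnostic_indices(confusion_matrix(tp = 28, fp = 1, tn = 6, fn = 1))
diagnostic_indices <- function(cm, ci_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  z <- qnorm(1 - (1 - ci_level) / 2)
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  n1 <- tp + fn; n0 <- tn + fp; np <- tp + fp; nn <- tn + fn
  N <- n1 + n0

  prop <- function(x, n) if (n > 0) x / n else NA_real_
  cp <- function(x, n) if (n > 0) clopper_pearson(x, n, ci_level) else c(lo = NA_real_, hi = NA_real_)

  acc <- prop(tp + tn, N); acc_ci <- cp(tp + tn, N)
  sens <- prop(tp, n1);    sens_ci <- cp(tp, n1)
  spec <- prop(tn, n0);    spec_ci <- cp(tn, n0)
  ppv <- prop(tp, np)
  npv <- prop(tn, nn)

  # Mercaldo standard-logit variances (prevalence form)
  ppv_ci <- if (!is.na(ppv) && n1 > 0 && n0 > 0 && tp > 0 && fp > 0) {
    logit_ci(ppv, (1 - sens) / (n1 * sens) + spec / (n0 * (1 - spec)), z)
  } else c(lo = NA_real_, hi = NA_real_)
  npv_ci <- if (!is.na(npv) && n1 > 0 && n0 > 0 && tn > 0 && fn > 0) {
    logit_ci(npv, sens / (n1 * (1 - sens)) + (1 - spec) / (n0 * spec), z)
  } else c(lo = NA_real_, hi = NA_real_)

  plr <- if (!is.na(sens) && !is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_
  nlr <- if (!is.na(sens) && !is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_

  # Simel log-method intervals
  simel <- function(lr, var_log) {
    if (is.na(lr) || !is.finite(var_log) || lr <= 0) return(c(lo = NA_real_, hi = NA_real_))
    c(lo = lr * exp(-z * sqrt(var_log)), hi = lr * exp(z * sqrt(var_log)))
  }
  plr_ci <- if (tp > 0 && fp > 0) simel(plr, (1 - sens) / tp + spec / fp) else c(lo = NA_real_, hi = NA_real_)
  nlr_ci <- if (fn > 0 && tn > 0) simel(nlr, sens / fn + (1 - spec) / tn) else c(lo = NA_real_, hi = NA_real_)

  structure(
    list(
      cm = cm, n = N, ci_level = ci_level,
      accuracy_pct = 100 * acc, accuracy_ci_pct = 100 * acc_ci,
      sensitivity_pct = 100 * sens, sensitivity_ci_pct = 100 * sens_ci,
      specificity_pct = 100 * spec, specificity_ci_pct = 100 * spec_ci,
      ppv_pct = 100 * ppv, ppv_ci_pct = 100 * ppv_ci,
      npv_pct = 100 * npv, npv_ci_pct = 100 * npv_ci,
      plr = plr, plr_ci = plr_ci,
      nlr = nlr, nlr_ci = nlr_ci,
      youden = sens + spec - 1,
      false_discovery_rate_pct = 100 * (1 - ppv),
      false_omission_rate_pct = 100 * (1 - npv),
      misclassified_pct = 100 * prop(fp + fn, N)
    ),
    class = "diagnostic_indices"
  )
}

#' @export
tidy.diagnostic_indices <- function(x, ...) {
  tibble(
    statistic = c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                  "plr", "nlr", "youden", "false_discovery_rate",
                  "false_omission_rate", "misclassified"),
    estimate = c(x$accuracy_pct, x$sensitivity_pct, x$specificity_pct,
                 x$ppv_pct, x$npv_pct, x$plr, x$nlr, x$youden,
                 x$false_discovery_rate_pct, x$false_omission_rate_pct,
                 x$misclassified_pct),
    conf.low = c(x$accuracy_ci_pct[1], x$sensitivity_ci_pct[1],
                 x$specificity_ci_pct[1], x$ppv_ci_pct[1], x$npv_ci_pct[1],
                 x$plr_ci[1], x$nlr_ci[1], NA, NA, NA, NA),
    conf.high = c(x$accuracy_ci_pct[2], x$sensitivity_ci_pct[2],
                  x$specificity_ci_pct[2], x$ppv_ci_pct[2], x$npv_ci_pct[2],
                  x$plr_ci[2], x$nlr_ci[2], NA, NA, NA, NA),
    unit = c(rep("percent", 5), "ratio", "ratio", "unitless",
             "percent", "percent", "percent")
  )
}

#' @export
print.diagnostic_indices <- function(x, ...) {
  cat(sprintf("<diagnostic_indices> n = %d (TP %d, FP %d, TN %d, FN %d)\n",
              x$n, x$cm$tp, x$cm$fp, x$cm$tn, x$cm$fn))
  f <- function(lab, est, ci) {
    cat(sprintf("  %-28s %s (%s-%s)\n", lab, fmt_num(est, 1),
                fmt_num(ci[1], 1), fmt_num(ci[2], 1)))
  }
  f("Accuracy, %", x$accuracy_pct, x$accuracy_ci_pct)
  f("Sensitivity, %", x$sensitivity_pct, x$sensitivity_ci_pct)
  f("Specificity, %", x$specificity_pct, x$specificity_ci_pct)
  f("Positive predictive value, %", x$ppv_pct, x$ppv_ci_pct)
  f("Negative predictive value, %", x$npv_pct, x$npv_ci_pct)
  cat(sprintf("  %-28s %s (%s-%s)\n", "Positive likelihood ratio",
              fmt_num(x$plr, 2), fmt_num(x$plr_ci[1], 2), fmt_num(x$plr_ci[2], 2)))
  cat(sprintf("  %-28s %s (%s-%s)\n", "Negative likelihood ratio",
              fmt_num(x$nlr, 2), fmt_num(x$nlr_ci[1], 2), fmt_num(x$nlr_ci[2], 2)))
  cat(sprintf("  %-28s %s\n", "Youden index", fmt_num(x$youden, 3)))
  invisible(x)
}

# half-up rounding for report formatting (clinical reporting convention)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt_num <- function(x, digits) {
  if (is.na(x)) return("NA")
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' ROC analysis of an index against invasive positivity
#'
#' Sweeps cutoffs over the unique index values (a lower index calls disease);
#' AUC is the Mann-Whitney concordance probability with ties counted 1/2
#' (identical to the trapezoid area under the empirical ROC). The reported
#' optimal cutoff maximizes the Youden index over the union of the observed
#' values and a 0.01-step grid on [0.50, 0.95]; exact ties are broken toward
#' the cutoff nearest 0.80, then toward the larger cutoff.
#'
#' @param cohort A [paired_cohort()].
#' @param ffr_threshold Invasive positivity threshold (default 0.80).
#' @param grid Cutoff grid added to the observed values for optimal-cutoff
#'   reporting.
#' @return An object of class `roc_result` with fields `auc`, `sweep`
#'   (tibble: `cutoff`, `sens`, `spec`, `youden`), `optimal_cutoff`,
#'   `optimal_sens`, `optimal_spec`, `optimal_youden`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(cohort, ffr_threshold = 0.80,
                         grid = seq(0.50, 0.95, by = 0.01)) {
  cohort <- as_paired_cohort(cohort)
  truth <- cohort$invasive_ffr <= ffr_threshold
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) {
    abort("ROC analysis needs at least one positive and one negative vessel.")
  }
  x <- cohort$index_value
  # Mann-Whitney with ties 1/2; positives are expected to have LOWER index
  r <- rank(x, ties.method = "average")
  auc <- 1 - (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  sweep_at <- function(cut) {
    pred <- x <= cut
    c(sens = sum(pred & truth) / n1, spec = sum(!pred & !truth) / n0)
  }
  cuts <- sort(unique(c(x, grid)))
  ss <- vapply(cuts, sweep_at, numeric(2))
  sweep <- tibble(cutoff = cuts, sens = ss["sens", ], spec = ss["spec", ],
                  youden = ss["sens", ] + ss["spec", ] - 1)
  best <- max(sweep$youden)
  tied <- which(abs(sweep$youden - best) < 1e-12)
  if (length(tied) > 1L) {
    d080 <- abs(sweep$cutoff[tied] - 0.80)
    tied <- tied[d080 == min(d080)]
    tied <- tied[which.max(sweep$cutoff[tied])]
  }
  structure(
    list(auc = auc, sweep = sweep,
         optimal_cutoff = sweep$cutoff[tied],
         optimal_sens = sweep$sens[tied],
         optimal_spec = sweep$spec[tied],
         optimal_youden = sweep$youden[tied],
         n_pos = n1, n_neg = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d pos / %d neg); optimal cutoff %.2f (sens %.1f%%, spec %.1f%%, Youden %.3f)\n",
              x$auc, x$n_pos, x$n_neg, x$optimal_cutoff,
              100 * x$optimal_sens, 100 * x$optimal_spec, x$optimal_youden))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$sweep

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, optimal_cutoff = x$optimal_cutoff,
         optimal_sens = x$optimal_sens, optimal_spec = x$optimal_spec,
         optimal_youden = x$optimal_youden, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
autoplot.roc_result <- function(object, ...) {
  df <- dplyr::arrange(object$sweep, 1 - .data$spec, .data$sens)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$spec, y = .data$sens)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Correlation between two paired measurement series
#'
#' Pearson product-moment or Spearman rank correlation with the p-value from
#' the t transform, as used for agreement of image-derived indices with
#' invasive FFR.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `r`, `p_value`, `method`, `n`.
#' @export
paired_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("Correlation needs at least 3 pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance: correlation undefined.")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble(r = unname(ct$estimate), p_value = ct$p.value,
         method = method, n = length(x))
}

#' Bland-Altman agreement summary
#'
#' Differences `d = x - y`; limits of agreement are
#' `mean(d) +/- 1.96 * sd(d)` with the sample (n-1) standard deviation of
#' the signed differences.
#'
#' @param x,y Equal-length numeric vectors (length >= 2): the two
#'   measurements of the same quantity.
#' @return An object of class `agreement_summary` with `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, and the per-pair `differences` and
#'   `means` retained for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2L) abort("Agreement needs at least 2 pairs.")
  d <- x - y
  m <- mean(d)
  s <- sd(d)
  structure(
    list(mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         differences = d, means = (x + y) / 2, n = length(d)),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> mean diff %.4f, SD %.4f, LoA (%.4f, %.4f), n = %d\n",
              x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @export
tidy.agreement_summary <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' @export
autoplot.agreement_summary <- function(object, ...) {
  df <- tibble(mean = object$means, diff = object$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Mean of paired measurements", y = "Difference") +
    ggplot2::theme_minimal()
}

#' Side-by-side diagnostic comparison of two index methods
#'
#' Evaluates two paired cohorts (sharing the same vessels and invasive FFR
#' column) at a fixed cutoff: the full diagnostic-index panel for each,
#' ROC/AUC, Pearson correlation with invasive FFR, Bland-Altman agreement
#' with invasive FFR, and inter-method correlation/agreement.
#'
#' @param cohort_a,cohort_b [paired_cohort()]s over the same vessel ids.
#' @param cutoff Index cutoff applied to both methods (default 0.80).
#' @param ffr_threshold Invasive positivity threshold (default 0.80).
#' @param ci_level Confidence level for all intervals.
#' @param labels Length-2 character, method display names.
#' @return An object of class `method_comparison`.
#' @export
compare_methods <- function(cohort_a, cohort_b, cutoff = 0.80,
                            ffr_threshold = 0.80, ci_level = 0.95,
                            labels = c("method_a", "method_b")) {
  cohort_a <- as_paired_cohort(cohort_a)
  cohort_b <- as_paired_cohort(cohort_b)
  if (!setequal(cohort_a$vessel_id, cohort_b$vessel_id)) {
    abort("The two cohorts must cover the same vessel ids.")
  }
  cohort_b <- cohort_b[match(cohort_a$vessel_id, cohort_b$vessel_id), ]
  one <- function(co) {
    list(
      cm = confusion_at_cutoff(co, cutoff, ffr_threshold),
      roc = roc_analysis(co, ffr_threshold),
      cor_ffr = paired_correlation(co$index_value, co$invasive_ffr),
      ba_ffr = bland_altman(co$index_value, co$invasive_ffr)
    )
  }
  a <- one(cohort_a); b <- one(cohort_b)
  structure(
    list(
      labels = labels, cutoff = cutoff, ffr_threshold = ffr_threshold,
      indices_a = diagnostic_indices(a$cm, ci_level),
      indices_b = diagnostic_indices(b$cm, ci_level),
      roc_a = a$roc, roc_b = b$roc,
      cor_a = a$cor_ffr, cor_b = b$cor_ffr,
      ba_a = a$ba_ffr, ba_b = b$ba_ffr,
      cor_ab = paired_correlation(cohort_a$index_value, cohort_b$index_value),
      ba_ab = bland_altman(cohort_a$index_value, cohort_b$index_value)
    ),
    class = "method_comparison"
  )
}

#' @export
tidy.method_comparison <- function(x, ...) {
  ta <- tidy(x$indices_a) |> dplyr::mutate(method = x$labels[1])
  tb <- tidy(x$indices_b) |> dplyr::mutate(method = x$labels[2])
  extra <- tibble(
    statistic = rep(c("auc", "r_vs_ffr", "ba_mean_diff"), 2),
    estimate = c(x$roc_a$auc, x$cor_a$r, x$ba_a$mean_diff,
                 x$roc_b$auc, x$cor_b$r, x$ba_b$mean_diff),
    conf.low = NA_real_, conf.high = NA_real_,
    unit = rep(c("auc", "r", "diff"), 2),
    method = rep(x$labels, each = 3)
  )
  dplyr::bind_rows(ta, tb, extra) |>
    dplyr::select("method", dplyr::everything())
}

#' Markdown report of a two-method comparison
#'
#' Emits the comparison as a Markdown table with the conventional row labels
#' of diagnostic-performance tables (each cell
#' `estimate (CI low - CI high)`), percentages half-up rounded to 1 decimal,
#' ratios to 2, AUC to 3.
#'
#' @param x A `method_comparison`.
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(x) {
  stopifnot(inherits(x, "method_comparison"))
  cell <- function(est, ci, d) {
    sprintf("%s (%s-%s)", fmt_num(est, d), fmt_num(ci[1], d), fmt_num(ci[2], d))
  }
  row <- function(label, fa, fb) sprintf("| %s | %s | %s |", label, fa, fb)
  ia <- x$indices_a; ib <- x$indices_b
  lines <- c(
    sprintf("| Statistic | %s <= %.2f | %s <= %.2f |",
            x$labels[1], x$cutoff, x$labels[2], x$cutoff),
    "| --- | --- | --- |",
    row("Accuracy, %", cell(ia$accuracy_pct, ia$accuracy_ci_pct, 1),
        cell(ib$accuracy_pct, ib$accuracy_ci_pct, 1)),
    row("Sensitivity, %", cell(ia$sensitivity_pct, ia$sensitivity_ci_pct, 1),
        cell(ib$sensitivity_pct, ib$sensitivity_ci_pct, 1)),
    row("Specificity, %", cell(ia$specificity_pct, ia$specificity_ci_pct, 1),
        cell(ib$specificity_pct, ib$specificity_ci_pct, 1)),
    row("Positive predictive value, %", cell(ia$ppv_pct, ia$ppv_ci_pct, 1),
        cell(ib$ppv_pct, ib$ppv_ci_pct, 1)),
    row("Negative predictive value, %", cell(ia$npv_pct, ia$npv_ci_pct, 1),
        cell(ib$npv_pct, ib$npv_ci_pct, 1)),
    row("Positive likelihood ratio", cell(ia$plr, ia$plr_ci, 2),
        cell(ib$plr, ib$plr_ci, 2)),
    row("Negative likelihood ratio", cell(ia$nlr, ia$nlr_ci, 2),
        cell(ib$nlr, ib$nlr_ci, 2)),
    row("Youden index", fmt_num(ia$youden, 3), fmt_num(ib$youden, 3)),
    row("AUC", fmt_num(x$roc_a$auc, 3), fmt_num(x$roc_b$auc, 3)),
    row("Correlation with FFR (R)", fmt_num(x$cor_a$r, 4), fmt_num(x$cor_b$r, 4)),
    row("Misclassified, %", fmt_num(ia$misclassified_pct, 1),
        fmt_num(ib$misclassified_pct, 1))
  )
  lines
}
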