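# Patient-level aggregation and cohort statistics: ANOVA, ROC/AUC with
# bootstrap CI and Youden cutoff, Kaplan-Meier, dichotomized and
# stratified sensitivity/specificity, histograms, and helpers for
# reconstructing contingency tables from printed percentages.

#' Aggregate ROI-level anisotropy to patient level
#'
#' @param measurements data.frame with columns `patient_id` and `g`
#'   (plus `f_grad`, `f_var`, `n_pixels` for the pooled method).
#' @param method `"mean"` (default), `"median"`, or `"pooled"`
#'   (recompute g from pixel-count-weighted mean gradient intensity and
#'   variance).
#' @param config An [imaging_config()] (used by `"pooled"`).
#' @return data.frame with `patient_id`, `g_patient`, `n_rois`.
#'   Patients whose measurements are all missing are dropped with a
#'   warning.
#' @export
aggregate_patient_g <- function(measurements, method = c("mean", "median", "pooled"),
                                config = imaging_config()) {
  method <- match.arg(method)
  if (!all(c("patient_id", "g") %in% names(measurements))) {
    stopf("`measurements` needs columns patient_id and g")
  }
  keep <- !is.na(measurements$g)
  if (!all(keep)) {
    dropped <- unique(measurements$patient_id[!keep])
    measurements <- measurements[keep, , drop = FALSE]
    gone <- setdiff(dropped, measurements$patient_id)
    if (length(gone)) {
      warnf("excluding %d patient(s) with no valid measurements: %s",
            length(gone), paste(gone, collapse = ", "))
    }
  }
  split_idx <- split(seq_len(nrow(measurements)), measurements$patient_id)
  g_patient <- vapply(split_idx, function(ix) {
    sub <- measurements[ix, , drop = FALSE]
    switch(method,
      mean = mean(sub$g),
      median = stats::median(sub$g),
      pooled = {
        if (!all(c("f_grad", "f_var", "n_pixels") %in% names(sub))) {
          stopf("pooled aggregation needs f_grad, f_var and n_pixels columns")
        }
        w <- sub$n_pixels
        compute_g(sum(w * sub$f_grad) / sum(w), sum(w * sub$f_var) / sum(w), config)
      }
    )
  }, numeric(1))
  data.frame(
    patient_id = names(split_idx),
    g_patient = unname(g_patient),
    n_rois = lengths(split_idx),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' One-way ANOVA
#'
#' Classical equal-variance one-way ANOVA F test across groups.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return List with `F`, `p`, and degrees of freedom `df1`, `df2`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stopf("need at least two groups")
  if (any(lengths(groups) < 2)) stopf("each group needs at least two values")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), lengths(groups)))
  within_var <- vapply(groups, stats::var, numeric(1))
  if (all(within_var == 0)) {
    stopf("degenerate input: zero within-group variance in every group")
  }
  fit <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  list(
    F = unname(fit$statistic),
    p = unname(fit$p.value),
    df1 = unname(fit$parameter[1]),
    df2 = unname(fit$parameter[2])
  )
}

#' Rank-based AUC (Mann-Whitney), ties counted one half
#'
#' @param scores Numeric scores, higher = more positive call.
#' @param labels Logical/0-1 vector; `TRUE` marks the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present")
  r <- rank(scores)  # midranks handle ties at 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong variance of the AUC via placement values.
delong_ci <- function(scores, labels, conf = 0.95) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  m <- length(pos); n <- length(neg)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  auc <- mean(v10)
  s2 <- stats::var(v10) / m + stats::var(v01) / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(max(0, auc - z * sqrt(s2)), min(1, auc + z * sqrt(s2)))
}

#' ROC analysis with bootstrap CI and Youden-optimal cutoff
#'
#' The AUC uses the rank (Mann-Whitney) method with ties counted one
#' half.  The confidence interval is a stratified bootstrap percentile
#' interval by default (cases and controls resampled separately);
#' DeLong's asymptotic interval is available via `ci_method`.  The
#' optimal operating point maximizes the Youden index `J = sens + spec
#' - 1`; the reported cutoff is the midpoint between the adjacent
#' observed scores bracketing it, on the original score scale.
#'
#' @param scores Numeric predictor values.
#' @param labels Logical/0-1; `TRUE` = positive class (recurrence).
#' @param orientation `"higher"` if larger scores indicate the positive
#'   class (PSA, Gleason, CAPRA-S) or `"lower"` (anisotropy: low g
#'   indicates recurrence).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap.
#' @param ci_method `"bootstrap"` (default) or `"delong"`.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `roc_result`: list with `auc`, `auc_ci`,
#'   `curve` (threshold, sensitivity, specificity), `optimal_cutoff`,
#'   `sensitivity`, `specificity` (at the optimum), `orientation`.
#' @export
roc_analysis <- function(scores, labels, orientation = c("higher", "lower"),
                         n_boot = 2000L, seed = 1L,
                         ci_method = c("bootstrap", "delong"), conf = 0.95) {
  orientation <- match.arg(orientation)
  ci_method <- match.arg(ci_method)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stopf("`scores` and `labels` lengths differ")
  if (anyNA(scores) || anyNA(labels)) stopf("scores/labels must not contain NA")
  if (!any(labels) || all(labels)) stopf("both classes must be present")
  s <- if (orientation == "lower") -scores else scores

  auc <- auc_rank(s, labels)
  uq <- sort(unique(s))
  thr <- c(-Inf, (uq[-1] + uq[-length(uq)]) / 2, Inf)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  sens <- vapply(thr, function(t) sum(s > t & labels) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(s <= t & !labels) / n_neg, numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)
  cutoff_internal <- thr[best]
  optimal_cutoff <- if (orientation == "lower") -cutoff_internal else cutoff_internal

  auc_ci <- if (ci_method == "delong") {
    delong_ci(s, labels, conf)
  } else {
    idx_pos <- which(labels)
    idx_neg <- which(!labels)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        take <- c(sample(idx_pos, n_pos, replace = TRUE),
                  sample(idx_neg, n_neg, replace = TRUE))
        auc_rank(s[take], labels[take])
      }, numeric(1))
    })
    unname(stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }

  structure(
    list(
      auc = auc, auc_ci = auc_ci,
      curve = data.frame(threshold = thr, sensitivity = sens, specificity = spec),
      optimal_cutoff = optimal_cutoff,
      sensitivity = sens[best], specificity = spec[best],
      orientation = orientation, ci_method = ci_method,
      n_pos = n_pos, n_neg = n_neg
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (%d%% CI %.3f-%.3f, %s), cutoff %.4g: sens %.1f%% spec %.1f%%\n",
    x$auc, 95, x$auc_ci[1], x$auc_ci[2], x$ci_method,
    x$optimal_cutoff, 100 * x$sensitivity, 100 * x$specificity
  ))
  invisible(x)
}

#' Sensitivity and specificity at a fixed threshold
#'
#' With `orientation = "lower"` (anisotropy) a value strictly below the
#' threshold predicts the positive class; with `"higher"` a value
#' strictly above does.
#'
#' @param values Predictor values.
#' @param labels Logical/0-1 positives.
#' @param threshold Finite decision threshold.
#' @param orientation `"lower"` (default, anisotropy convention) or
#'   `"higher"`.
#' @return List with `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_at_threshold <- function(values, labels, threshold,
                                   orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  if (!is.finite(threshold)) stopf("`threshold` must be finite")
  labels <- as.logical(labels)
  pred <- if (orientation == "lower") values < threshold else values > threshold
  tp <- sum(pred & labels)
  fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels)
  list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] (deaths before censorings at tied times)
#' into a tidy step-function table.
#'
#' @param times Non-negative follow-up times.
#' @param events Logical/0-1 event indicators.
#' @param group Optional label attached to the curve.
#' @return Object of class `km_curve`: data.frame with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, and attribute `group`.
#' @export
km_estimate <- function(times, events, group = NULL) {
  if (!length(times)) stopf("empty group")
  if (any(times < 0)) stopf("`times` must be non-negative")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  out <- data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  class(out) <- c("km_curve", "data.frame")
  attr(out, "group") <- group
  out
}

#' Survival probability at given times by step lookup
#'
#' @param km A [km_estimate()] result.
#' @param at Times at which to evaluate the step function.
#' @return Survival probabilities (1 before the first event time).
#' @export
km_survival_at <- function(km, at) {
  vapply(at, function(t) {
    idx <- which(km$time <= t)
    if (!length(idx)) 1 else km$survival[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' @param times,events Follow-up times and event flags.
#' @param group Two-level grouping vector.
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stopf("log-rank test needs exactly two groups")
  if (any(table(group) == 0)) stopf("empty group")
  fit <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  df <- length(fit$n) - 1
  list(chisq = fit$chisq, df = df, p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Stratified sensitivity/specificity of dichotomized anisotropy
#'
#' Within each stratum, patients are split at the anisotropy threshold
#' (`g < threshold` = "low" = predicted recurrent) and cross-tabulated
#' against the recurrence label.
#'
#' @param cohort data.frame with the anisotropy, label and stratum
#'   columns.
#' @param stratum_col Name of the stratum column (e.g. a Gleason or
#'   CAPRA-S group factor).
#' @param g_threshold Decision threshold (default 0.93).
#' @param g_col,label_col Column names (defaults `g_patient`,
#'   `recurrent`).
#' @return data.frame with one row per stratum: `stratum`, `n`,
#'   `n_recurrent`, `recurrence_probability`, the four cell counts
#'   `low_rec`, `low_nonrec`, `high_rec`, `high_nonrec`, `sensitivity`,
#'   `specificity` (NA where a denominator is empty).  Empty strata are
#'   emitted with `n = 0` and NA rates.
#' @export
stratified_performance <- function(cohort, stratum_col, g_threshold = 0.93,
                                   g_col = "g_patient", label_col = "recurrent") {
  for (cl in c(stratum_col, g_col, label_col)) {
    if (!cl %in% names(cohort)) stopf("cohort lacks column '%s'", cl)
  }
  strata <- cohort[[stratum_col]]
  if (!is.factor(strata)) strata <- factor(strata)
  rows <- lapply(levels(strata), function(s) {
    sub <- cohort[strata == s & !is.na(strata), , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(
        stratum = s, n = 0L, n_recurrent = 0L, recurrence_probability = NA_real_,
        low_rec = 0L, low_nonrec = 0L, high_rec = 0L, high_nonrec = 0L,
        sensitivity = NA_real_, specificity = NA_real_, stringsAsFactors = FALSE
      ))
    }
    cm <- confusion_at_threshold(sub[[g_col]], sub[[label_col]],
                                 g_threshold, orientation = "lower")
    data.frame(
      stratum = s, n = nrow(sub), n_recurrent = sum(sub[[label_col]]),
      recurrence_probability = mean(as.logical(sub[[label_col]])),
      low_rec = cm$tp, low_nonrec = cm$fp, high_rec = cm$fn, high_nonrec = cm$tn,
      sensitivity = cm$sensitivity, specificity = cm$specificity,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Integer cell count from a printed percentage
#'
#' Reconstructs `round_half_up(n * percent / 100)`, the integer count
#' behind a percentage printed for a group of known size.
#'
#' @param n Group size.
#' @param percent Printed percentage (0-100).
#' @return Integer count.
#' @export
#' @examples
#' counts_from_rate(26, 26.9) # 7
counts_from_rate <- function(n, percent) {
  if (any(percent < 0 | percent > 100)) stopf("`percent` must be in [0, 100]")
  as.integer(round_half_up(n * percent / 100))
}

#' Histogram with fixed-width bins aligned to the origin
#'
#' Left-closed, right-open bins `[k * bin, (k + 1) * bin)` aligned to
#' multiples of the bin size (default 0.02, the convention used for
#' anisotropy histograms).
#'
#' @param values Numeric vector.
#' @param bin_size Positive bin width.
#' @return data.frame with `bin_left`, `bin_right`, `count`; counts sum
#'   to `length(values)`.
#' @export
histogram_g <- function(values, bin_size = 0.02) {
  if (bin_size <= 0) stopf("`bin_size` must be positive")
  idx <- floor(values / bin_size + 1e-9)
  tab <- table(idx)
  ks <- as.integer(names(tab))
  data.frame(
    bin_left = ks * bin_size,
    bin_right = (ks + 1) * bin_size,
    count = as.integer(tab)
  )
}
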