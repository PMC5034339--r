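# Cohort statistics: aggregation, ANOVA, ROC, KM, strata, histograms.

test_that("patient aggregation honours its method argument", {
  m <- data.frame(patient_id = c("a", "b", "b", "c", "c", "c"),
                  g = c(0.9, 0.90, 0.94, 0.91, 0.93, 0.95))
  expect_equal(aggregate_patient_g(m, "mean")$g_patient, c(0.9, 0.92, 0.93))
  expect_equal(aggregate_patient_g(m, "median")$g_patient[3], 0.93)
  # single ROI: that value under any method
  one <- m[1, ]
  one$f_grad <- 10; one$f_var <- 1; one$n_pixels <- 100
  for (meth in c("mean", "median", "pooled")) {
    expect_equal(aggregate_patient_g(one, meth)$g_patient,
                 if (meth == "pooled") compute_g(10, 1) else 0.9)
  }
})

test_that("patients with only missing measurements are dropped with a warning", {
  m <- data.frame(patient_id = c("a", "a", "b"), g = c(0.9, 0.92, NA))
  expect_warning(out <- aggregate_patient_g(m), "b")
  expect_equal(out$patient_id, "a")
})

test_that("one-way ANOVA reproduces the hand-computed F", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$F, 1.5, tolerance = 1e-12)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)
  expect_equal(res$p, stats::pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  # identical group means: F ~ 0, p ~ 1
  same <- one_way_anova(list(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_error(one_way_anova(list(1:3)), "two groups")
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
})

test_that("ANOVA F equals the brute-force sums-of-squares decomposition", {
  set.seed(123)
  for (i in 1:25) {
    groups <- lapply(seq_len(sample(2:4, 1)),
                     function(k) rnorm(sample(3:10, 1), mean = runif(1)))
    res <- one_way_anova(groups)
    all_v <- unlist(groups)
    grand <- mean(all_v)
    ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - grand)^2)
    ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
    k <- length(groups); n <- length(all_v)
    expect_equal(res$F, (ssb / (k - 1)) / (ssw / (n - k)), tolerance = 1e-10)
  }
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(321)
  ps <- replicate(1000, {
    one_way_anova(list(rnorm(20), rnorm(20)))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("rank AUC matches brute-force pair counting", {
  expect_equal(auc_rank(c(0.9, 0.4, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc_rank(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  set.seed(14)
  for (i in 1:60) {
    n <- sample(4:200, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    expect_equal(auc_rank(scores, labels), bf_auc(scores, labels), tolerance = 1e-12)
    expect_equal(auc_rank(scores, labels) + auc_rank(-scores, labels), 1,
                 tolerance = 1e-12)
  }
})

test_that("roc_analysis handles orientation, CI and the Youden cutoff", {
  set.seed(20)
  g <- c(rnorm(40, 0.91, 0.03), rnorm(80, 0.935, 0.025))
  labels <- rep(c(TRUE, FALSE), c(40, 80))
  r_lower <- roc_analysis(g, labels, "lower", n_boot = 400, seed = 2)
  r_higher <- roc_analysis(-g, labels, "higher", n_boot = 400, seed = 2)
  expect_equal(r_lower$auc, r_higher$auc, tolerance = 1e-12)
  expect_equal(r_lower$auc, bf_auc(-g, labels), tolerance = 1e-12)
  expect_true(r_lower$auc_ci[1] <= r_lower$auc && r_lower$auc <= r_lower$auc_ci[2])
  # cutoff lies strictly between observed scores, on the g scale
  expect_false(r_lower$optimal_cutoff %in% g)
  expect_true(r_lower$optimal_cutoff > min(g) && r_lower$optimal_cutoff < max(g))
  # the reported operating point is attained by thresholding at the cutoff
  cm <- confusion_at_threshold(g, labels, r_lower$optimal_cutoff, "lower")
  expect_equal(cm$sensitivity, r_lower$sensitivity)
  expect_equal(cm$specificity, r_lower$specificity)
  expect_error(roc_analysis(g, rep(TRUE, 120)), "both classes")
})

test_that("perfectly separated scores give AUC 1 and a perfect cutoff", {
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3), "higher",
                    n_boot = 100)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
})

test_that("rank AUC and DeLong CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- rnorm(150)
  labels <- runif(150) < 0.3
  scores[labels] <- scores[labels] + 0.8
  ref <- suppressMessages(pROC::roc(labels, scores, direction = "<"))
  expect_equal(auc_rank(scores, labels), as.numeric(ref$auc), tolerance = 1e-10)
  ours <- roc_analysis(scores, labels, "higher", ci_method = "delong")
  ref_ci <- as.numeric(suppressMessages(pROC::ci.auc(ref, method = "delong")))
  expect_equal(ours$auc_ci[1], ref_ci[1], tolerance = 1e-6)
  expect_equal(ours$auc_ci[2], ref_ci[3], tolerance = 1e-6)
})

test_that("confusion_at_threshold reproduces the stratum operating points", {
  # counts reconstructed from the printed per-stratum recurrence rates
  g34 <- c(rep(0.9, 7 + 19), rep(0.95, 4 + 59))
  l34 <- c(rep(TRUE, 7), rep(FALSE, 19), rep(TRUE, 4), rep(FALSE, 59))
  cm <- confusion_at_threshold(g34, l34, 0.93, "lower")
  expect_equal(cm$tp, 7); expect_equal(cm$fn, 4)
  expect_equal(cm$tn, 59); expect_equal(cm$fp, 19)
  expect_equal(100 * cm$sensitivity, 63.6, tolerance = 0.05)
  expect_equal(round_half_up(100 * cm$specificity), 76)

  g43 <- c(rep(0.9, 5 + 3), rep(0.95, 1 + 5))
  l43 <- c(rep(TRUE, 5), rep(FALSE, 3), rep(TRUE, 1), rep(FALSE, 5))
  cm43 <- confusion_at_threshold(g43, l43, 0.93, "lower")
  expect_equal(100 * cm43$sensitivity, 83.3, tolerance = 0.05)
  expect_equal(100 * cm43$specificity, 62.5, tolerance = 1e-9)

  # all positives below and negatives above: perfect separation
  cm0 <- confusion_at_threshold(c(0.9, 0.91, 0.95, 0.96), c(TRUE, TRUE, FALSE, FALSE),
                                0.93, "lower")
  expect_equal(cm0$sensitivity, 1)
  expect_equal(cm0$specificity, 1)
  expect_error(confusion_at_threshold(1:3, c(TRUE, FALSE, TRUE), Inf), "finite")
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # no events: flat at 1
  km1 <- km_estimate(c(2, 4, 7), c(0, 0, 0))
  expect_true(all(km1$survival == 1))
  expect_equal(km_survival_at(km1, c(0, 5, 10)), c(1, 1, 1))
  # everyone censored after the first event: curve stays at the first step
  km2 <- km_estimate(c(1, 2, 3, 4), c(1, 0, 0, 0))
  expect_equal(km_survival_at(km2, 10), 0.75)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(41)
  for (i in 1:20) {
    times <- sample(1:40, 25, replace = TRUE)
    km <- km_estimate(times, rep(1, 25))
    at <- sort(unique(times))
    expect_equal(km_survival_at(km, at), vapply(at, function(t) mean(times > t),
                                                numeric(1)))
  }
})

test_that("KM with censoring matches the hand estimator on random data", {
  set.seed(52)
  for (i in 1:20) {
    times <- round(rexp(40, 0.05), 1)
    events <- runif(40) < 0.6
    km <- km_estimate(times, events)
    ref <- hand_km(times, events)
    expect_equal(km_survival_at(km, ref$time), ref$survival, tolerance = 1e-12)
  }
})

test_that("log-rank test separates distinct hazards and respects symmetry", {
  set.seed(61)
  tA <- rexp(60, 0.02); tB <- rexp(60, 0.15)
  times <- c(tA, tB); events <- rep(1, 120)
  grp <- rep(c("A", "B"), each = 60)
  res <- logrank_test(times, events, grp)
  expect_lt(res$p, 1e-6)
  # relabelling the groups leaves the statistic unchanged
  res_swapped <- logrank_test(times, events, ifelse(grp == "A", "B", "A"))
  expect_equal(res_swapped$chisq, res$chisq, tolerance = 1e-12)
  expect_error(logrank_test(tA, rep(1, 60), rep("A", 60)), "two groups")
})

test_that("stratified performance cross-tabulates the dichotomized predictor", {
  df <- data.frame(
    g_patient = c(0.9, 0.91, 0.95, 0.96, 0.92, 0.97, 0.98),
    recurrent = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    grp = factor(c("a", "a", "a", "a", "b", "b", "c"), levels = c("a", "b", "c", "d"))
  )
  out <- stratified_performance(df, "grp")
  expect_equal(out$n, c(4L, 2L, 1L, 0L))
  a <- out[out$stratum == "a", ]
  expect_equal(c(a$low_rec, a$low_nonrec, a$high_rec, a$high_nonrec), c(1, 1, 1, 1))
  expect_equal(a$sensitivity, 0.5)
  # stratum with only high-anisotropy non-recurrent patients
  cstr <- out[out$stratum == "c", ]
  expect_equal(cstr$specificity, 1)
  expect_true(is.na(cstr$sensitivity))
  expect_true(is.na(out$sensitivity[out$stratum == "d"]))
  # cells always sum to n
  expect_equal(out$low_rec + out$low_nonrec + out$high_rec + out$high_nonrec, out$n)
})

test_that("counts_from_rate rounds half up at the printed precision", {
  expect_identical(counts_from_rate(26, 26.9), 7L)
  expect_identical(counts_from_rate(63, 6.3), 4L)
  expect_identical(counts_from_rate(14, 64.3), 9L)
  expect_error(counts_from_rate(10, 150), "percent")
})

test_that("histogram bins are aligned, half-open, and complete", {
  h <- histogram_g(0.93, 0.02)
  expect_equal(h$bin_left, 0.92)
  expect_equal(h$bin_right, 0.94)
  expect_equal(h$count, 1L)
  set.seed(71)
  x <- runif(500, 0.8, 1)
  h2 <- histogram_g(x)
  expect_equal(sum(h2$count), 500L)
  h3 <- histogram_g(x + 0.02)
  expect_equal(h3$count, h2$count)
  expect_equal(h3$bin_left, h2$bin_left + 0.02, tolerance = 1e-9)
})
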