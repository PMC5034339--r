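# Published validation-cohort summaries shipped with the package.
#
# The package cannot redistribute the clinical imaging data, but the
# printed stratum sizes, per-stratum recurrence percentages and
# operating-point statistics are themselves inputs: they pin down the
# integer contingency tables (via counts_from_rate) and let the
# statistics code be checked against the printed values.

pkg_extdata <- function(file) {
  system.file("extdata", file, package = "qpianiso", mustWork = TRUE)
}

#' Published per-stratum contingency rates
#'
#' Stratum sizes and recurrence percentages for the anisotropy
#' (low/high at g = 0.93) and CAPRA-S (0-2 / 3-5 / 6-11) splits within
#' each Gleason stratum, as printed for the 192-patient validation
#' cohort.
#'
#' @return data.frame with columns `gleason`, `classifier`, `level`,
#'   `n`, `recurrence_pct`.
#' @export
published_table1 <- function() {
  utils::read.csv(pkg_extdata("published_table1.csv"), stringsAsFactors = FALSE)
}

#' Published cohort composition
#'
#' @return Named numeric vector of cohort-level quantities (class
#'   sizes, Gleason margins, pathology-flag counts, per-stratum
#'   recurrence percentages).
#' @export
published_cohort_summary <- function() {
  df <- utils::read.csv(pkg_extdata("published_cohort.csv"), stringsAsFactors = FALSE)
  stats::setNames(df$value, df$quantity)
}

#' Published operating-point performance
#'
#' Printed sensitivity/specificity (in percent) of the anisotropy
#' classifier at the g = 0.93 cutoff, overall and per Gleason stratum,
#' with the comparison tolerance implied by each value's printed
#' precision (0.1 where the printed value reflects truncation rather
#' than rounding).
#'
#' @return data.frame with columns `stratum`, `metric`, `printed`,
#'   `tolerance`.
#' @export
published_performance <- function() {
  utils::read.csv(pkg_extdata("published_performance.csv"), stringsAsFactors = FALSE)
}

#' Reconstruct and verify the published contingency statistics
#'
#' Rebuilds the integer 2x2 tables behind the published per-stratum
#' recurrence percentages ([counts_from_rate()]), recomputes sensitivity
#' and specificity with [confusion_at_threshold()] on synthesized
#' score/label vectors realizing those counts, and compares each result
#' with the printed value at the tolerance of its printed precision.
#' Marginal consistency (stratum sizes, recurrent totals) is checked in
#' the same pass.
#'
#' @param g_threshold Dichotomization threshold (default 0.93).
#' @return data.frame of checks: `check`, `expected`, `computed`,
#'   `tolerance`, `pass`.
#' @export
verify_published_tables <- function(g_threshold = 0.93) {
  t1 <- published_table1()
  cohort <- published_cohort_summary()
  perf <- published_performance()
  checks <- list()
  add <- function(check, expected, computed, tolerance = 0) {
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, expected = expected, computed = computed,
      tolerance = tolerance, pass = abs(expected - computed) <= tolerance,
      stringsAsFactors = FALSE
    )
  }

  aniso <- t1[t1$classifier == "anisotropy", ]
  strata <- unique(aniso$gleason)
  rec_total <- 0L
  for (s in strata) {
    lo <- aniso[aniso$gleason == s & aniso$level == "low", ]
    hi <- aniso[aniso$gleason == s & aniso$level == "high", ]
    tp <- counts_from_rate(lo$n, lo$recurrence_pct)
    fn <- counts_from_rate(hi$n, hi$recurrence_pct)
    fp <- lo$n - tp
    tn <- hi$n - fn
    rec_total <- rec_total + tp + fn
    # realize the counts as g values around the threshold and recompute
    values <- c(rep(g_threshold - 0.01, tp + fp), rep(g_threshold + 0.01, fn + tn))
    labels <- c(rep(TRUE, tp), rep(FALSE, fp), rep(TRUE, fn), rep(FALSE, tn))
    cm <- confusion_at_threshold(values, labels, g_threshold, orientation = "lower")
    skey <- switch(s, "5-6" = "5_6", "3+4" = "3p4", "4+3" = "4p3", "8-10" = "8_10")
    add(sprintf("GS %s stratum size", s),
        cohort[[sprintf("gleason_%s", skey)]], lo$n + hi$n)
    for (m in c("sensitivity", "specificity")) {
      row <- perf[perf$stratum == s & perf$metric == m, ]
      if (nrow(row)) {
        add(sprintf("GS %s %s (%%)", s, m), row$printed, 100 * cm[[m]], row$tolerance)
      }
    }
    # stratum recurrence probability against the printed stratum rate
    add(sprintf("GS %s recurrence probability (%%)", s),
        cohort[[sprintf("gleason_%s_recurrence_pct", skey)]],
        100 * (tp + fn) / (lo$n + hi$n), 0.5)
  }
  add("recurrent patients reconstructed from strata", cohort[["n_recurrent"]], rec_total)
  add("cohort size from Gleason margins", cohort[["n_patients"]],
      sum(aniso$n))

  # CAPRA-S margins: per-stratum level sizes must sum to the stratum size
  capra <- t1[t1$classifier == "capra_s", ]
  for (s in unique(capra$gleason)) {
    add(sprintf("GS %s CAPRA-S margin", s),
        sum(aniso$n[aniso$gleason == s]),
        sum(capra$n[capra$gleason == s]))
  }

  # overall operating point: printed percentages of known class sizes
  # must correspond to integer counts that reproduce the percentages
  n_pos <- cohort[["n_recurrent"]]
  n_neg <- cohort[["n_nonrecurrent"]]
  sens_row <- perf[perf$stratum == "overall" & perf$metric == "sensitivity", ]
  spec_row <- perf[perf$stratum == "overall" & perf$metric == "specificity", ]
  tp <- counts_from_rate(n_pos, sens_row$printed)
  tn <- counts_from_rate(n_neg, spec_row$printed)
  values <- c(rep(g_threshold - 0.01, tp), rep(g_threshold + 0.01, n_pos - tp),
              rep(g_threshold - 0.01, n_neg - tn), rep(g_threshold + 0.01, tn))
  labels <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  cm <- confusion_at_threshold(values, labels, g_threshold, orientation = "lower")
  add("overall sensitivity (%)", sens_row$printed, 100 * cm$sensitivity, sens_row$tolerance)
  add("overall specificity (%)", spec_row$printed, 100 * cm$specificity, spec_row$tolerance)

  do.call(rbind, checks)
}
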