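# CAPRA-S: post-surgical recurrence risk points from PSA, Gleason
# patterns, and pathology flags, used as the comparator predictor.

capra_psa_points <- function(psa) {
  ifelse(psa <= 6, 0L, ifelse(psa <= 10, 1L, ifelse(psa <= 20, 2L, 3L)))
}

capra_gleason_points <- function(primary, secondary) {
  total <- primary + secondary
  ifelse(total >= 8, 3L,
    ifelse(primary >= 4, 2L,
      ifelse(secondary >= 4, 1L, 0L)
    )
  )
}

#' CAPRA-S points for a patient record
#'
#' Sums: PSA points (<= 6 ng/ml: 0; 6.01-10: 1; 10.01-20: 2; > 20: 3),
#' Gleason points (no pattern 4/5: 0; 3+4: 1; 4+3: 2; GS 8-10: 3),
#' positive surgical margins (+2), seminal vesicle invasion (+2),
#' extraprostatic extension (+1), and lymph node invasion (+1).
#' PSA bin edges are half-open at the printed boundaries (6.01 means
#' strictly above 6).  The rubric maximum is 12 points.
#'
#' @param psa Pre-surgical PSA in ng/ml.
#' @param gleason_primary,gleason_secondary Gleason growth patterns
#'   (1-5).
#' @param sm,svi,epe,lni Logical pathology flags: positive surgical
#'   margins, seminal vesicle invasion, extraprostatic extension, lymph
#'   node invasion.
#' @return Integer CAPRA-S points (vectorized).
#' @export
#' @examples
#' capra_s_points(4, 3, 3, FALSE, FALSE, FALSE, FALSE)    # 0
#' capra_s_points(5.6, 3, 4, FALSE, FALSE, FALSE, FALSE)  # 1
capra_s_points <- function(psa, gleason_primary, gleason_secondary,
                           sm, svi, epe, lni) {
  args <- list(psa = psa, gleason_primary = gleason_primary,
               gleason_secondary = gleason_secondary,
               sm = sm, svi = svi, epe = epe, lni = lni)
  for (nm in names(args)) {
    if (is.null(args[[nm]]) || anyNA(args[[nm]])) {
      stopf("CAPRA-S covariate '%s' is missing", nm)
    }
  }
  if (any(psa < 0)) stopf("`psa` must be non-negative")
  if (any(gleason_primary < 1 | gleason_primary > 5) ||
      any(gleason_secondary < 1 | gleason_secondary > 5)) {
    stopf("Gleason patterns must be in 1-5")
  }
  as.integer(
    capra_psa_points(psa) +
      capra_gleason_points(gleason_primary, gleason_secondary) +
      2L * as.integer(sm) + 2L * as.integer(svi) +
      1L * as.integer(epe) + 1L * as.integer(lni)
  )
}

#' CAPRA-S risk group from points
#'
#' 0-2 points: low; 3-5: intermediate; 6 or more: high.
#'
#' @param points Non-negative integer CAPRA-S points.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
capra_s_group <- function(points) {
  if (any(points < 0)) stopf("CAPRA-S points must be non-negative")
  factor(
    ifelse(points <= 2, "low", ifelse(points <= 5, "intermediate", "high")),
    levels = c("low", "intermediate", "high")
  )
}

#' Append CAPRA-S columns to a cohort table
#'
#' @param cohort data.frame with columns `psa`, `gleason_primary`,
#'   `gleason_secondary`, `sm`, `svi`, `epe`, `lni`.
#' @return The data.frame with `capra_s` and `capra_s_group` appended.
#' @export
add_capra_s <- function(cohort) {
  need <- c("psa", "gleason_primary", "gleason_secondary", "sm", "svi", "epe", "lni")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) stopf("cohort lacks columns: %s", paste(missing, collapse = ", "))
  cohort$capra_s <- capra_s_points(
    cohort$psa, cohort$gleason_primary, cohort$gleason_secondary,
    cohort$sm, cohort$svi, cohort$epe, cohort$lni
  )
  cohort$capra_s_group <- capra_s_group(cohort$capra_s)
  cohort
}

#' Gleason stratum label from growth patterns
#'
#' Groups into the standard prognostic strata `5-6`, `3+4`, `4+3`,
#' `8-10`.
#'
#' @param primary,secondary Gleason patterns (1-5).
#' @return Factor with the four stratum levels.
#' @export
gleason_stratum <- function(primary, secondary) {
  total <- primary + secondary
  out <- ifelse(total <= 6, "5-6",
    ifelse(total >= 8, "8-10", ifelse(primary <= 3, "3+4", "4+3"))
  )
  factor(out, levels = c("5-6", "3+4", "4+3", "8-10"))
}
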