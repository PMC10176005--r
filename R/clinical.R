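# NEDA-3 disease-activity scoring.
#
# EDSS is the ordinal 0-10 Expanded Disability Status Scale in 0.5 steps;
# 4.0 is the conventional ambulation milestone that switches the
# progression threshold.

.flagYes <- function(x) {
  x <- tolower(trimws(as.character(x)))
  !is.na(x) & x == "yes"
}

#' Sustained EDSS disability progression
#'
#' Progression is a 1.0-point increase when the baseline EDSS is at most
#' 4.0, and a 0.5-point increase when the baseline EDSS is strictly above
#' 4.0.
#'
#' @param baseline,follow EDSS scores (0-10 in 0.5 steps); vectorized.
#' @return Logical: progression occurred.
#' @examples
#' edssProgression(3.5, 4.5)  # TRUE
#' edssProgression(4.0, 4.5)  # FALSE: baseline <= 4 needs a full point
#' edssProgression(6.0, 6.5)  # TRUE
#' @export
edssProgression <- function(baseline, follow) {
  (baseline <= 4 & follow - baseline >= 1.0) |
  (baseline > 4 & follow - baseline >= 0.5)
}

#' NEDA-3: no evidence of disease activity over one evaluation interval
#'
#' NEDA-3 holds when there is no new clinical relapse, no MRI activity
#' (new or enlarged lesion) and no sustained EDSS progression. Missing
#' flags (`NA`, `"n/a"`) contribute no evidence of activity (relapses are
#' not recorded for progressive patients).
#'
#' @param edssBaseline,edssFollow EDSS at the start and end of the
#'   evaluation interval.
#' @param newLesion,relapse activity flags: `"yes"`, `"none"` or missing.
#' @return Logical: NEDA holds (no activity); vectorized.
#' @export
neda3 <- function(edssBaseline, edssFollow, newLesion, relapse) {
  !.flagYes(relapse) & !.flagYes(newLesion) &
    !edssProgression(edssBaseline, edssFollow)
}

#' Disease-activity status score for one clinical record
#'
#' NEDA-3 is evaluated at mid-interval (EDSS baseline to mid) and at the
#' end of the interscan interval (EDSS baseline to final, with the
#' baseline taken at T0 for both evaluations). The final status is 0
#' (clear disease progression) only when NEDA fails at both evaluations;
#' otherwise 1 (stable or improving).
#'
#' @param record list or one-row data.frame with fields `edss_t0`,
#'   `edss_mid`, `edss_t1`, `new_lesion_mid`, `relapse_mid`,
#'   `new_lesion_end`, `relapse_end`.
#' @return 0 or 1.
#' @export
diseaseStatusScore <- function(record) {
  scoreClinicalTable(as.data.frame(record))$status
}

#' Score a clinical table with the NEDA-3 composite rule
#'
#' @param clinical data.frame with the fields of [diseaseStatusScore()],
#'   one row per subject.
#' @return The input with `neda_mid`, `neda_end` (logical) and `status`
#'   (0/1) columns appended.
#' @examples
#' scoreClinicalTable(msCohortClinical())[, c("subject_id", "status")]
#' @export
scoreClinicalTable <- function(clinical) {
  needed <- c("edss_t0", "edss_mid", "edss_t1", "new_lesion_mid",
              "relapse_mid", "new_lesion_end", "relapse_end")
  missing <- setdiff(needed, names(clinical))
  if (length(missing))
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  clinical$neda_mid <- neda3(clinical$edss_t0, clinical$edss_mid,
                             clinical$new_lesion_mid, clinical$relapse_mid)
  clinical$neda_end <- neda3(clinical$edss_t0, clinical$edss_t1,
                             clinical$new_lesion_end, clinical$relapse_end)
  clinical$status <- ifelse(!clinical$neda_mid & !clinical$neda_end, 0L, 1L)
  clinical
}

#' Longitudinal clinical records of the 17-patient MS cohort
#'
#' The published clinical follow-up table of the study cohort: EDSS at
#' baseline, mid-interval and final scan, new-lesion and relapse flags per
#' evaluation interval, the interscan interval in months, and the NEDA and
#' final status values as reported (columns suffixed `_reported`).
#'
#' @return A data.frame with 17 rows.
#' @export
msCohortClinical <- function() {
  path <- system.file("extdata", "ms_cohort_clinical.csv",
                      package = "qmritrack", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
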