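# Lesion-by-lesion analysis of the four areas: long-format median table,
# area-by-time mixed model on the log scale, Tukey-adjusted pairwise
# area contrasts.

#' Build the long lesion-area median table
#'
#' For every enlarging lesion, extracts the median of each parameter over
#' the lesion's intersection with the focal FLAIR, initial peripheral and
#' later peripheral areas, from the T0 and T1 maps separately; NAWM
#' contributes one median per subject and timepoint. Medians are
#' log-transformed (natural log) for the downstream model, since qMRI
#' parameter medians are not normally distributed.
#'
#' @param mapsT0,mapsT1 [ParameterMaps-class] objects for the two
#'   sessions.
#' @param areas an [AreaMasks-class] object.
#' @param lesionIds integer labels of the enlarging lesions (from
#'   [selectEnlargingLesions()]).
#' @param subjectId subject identifier for the output rows.
#' @param parameters which parameters to extract.
#' @return data.frame with columns `subject_id`, `unit` (lesion label or
#'   `"NAWM"`), `area`, `timepoint`, `parameter`, `median`, `log_value`.
#'   Empty lesion-area intersections are omitted with a message; a
#'   non-positive median is an error (the log transform requires positive
#'   medians).
#' @export
buildLongTable <- function(mapsT0, mapsT1, areas, lesionIds,
                           subjectId = "sub-01", parameters = .PARAMETERS) {
  maps <- list(T0 = mapsT0, T1 = mapsT1)
  lab <- areas@lesionLabels
  areaMasks <- list(focal_flair = areas@focalFlair,
                    initial_peripheral = areas@initialPeripheral,
                    later_peripheral = areas@laterPeripheral)
  rows <- list()
  addRow <- function(unit, area, tp, param, m, mask) {
    vals <- .getParam(m, param)[mask]
    if (length(m@valid)) vals <- .getParam(m, param)[mask & m@valid]
    if (length(vals) == 0L) {
      message(sprintf("empty %s intersection for lesion %s; row omitted",
                      area, unit))
      return(NULL)
    }
    med <- stats::median(vals, na.rm = TRUE)
    if (!is.finite(med) || med <= 0)
      stop(sprintf("non-positive median (%s, %s, %s): log undefined",
                   unit, area, param))
    data.frame(subject_id = subjectId, unit = unit, area = area,
               timepoint = tp, parameter = param, median = med,
               log_value = log(med), stringsAsFactors = FALSE)
  }
  for (tp in c("T0", "T1")) {
    m <- maps[[tp]]
    for (param in parameters) {
      rows[[length(rows) + 1L]] <-
        addRow("NAWM", "nawm", tp, param, m, areas@nawm)
      for (id in lesionIds) {
        inLesion <- lab == id
        for (a in names(areaMasks))
          rows[[length(rows) + 1L]] <-
            addRow(as.character(id), a, tp, param, m,
                   inLesion & areaMasks[[a]])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the area-by-time mixed model for one parameter
#'
#' Linear mixed model on the log-transformed medians with fixed effects
#' for area (NAWM and the three lesion-related areas), timepoint, and
#' their interaction; a random intercept per participant; and a random
#' intercept per repeated series (one lesion-area or NAWM trajectory
#' measured at both timepoints), which with exactly two timepoints
#' carries the same single within-series correlation parameter as a
#' first-order autoregressive residual model (restricted to non-negative
#' correlation). F tests per fixed effect use Kenward-Roger denominator
#' degrees of freedom when pbkrtest is installed, otherwise Satterthwaite
#' (the method actually used is recorded in the result).
#'
#' @param longTable output of [buildLongTable()] (possibly concatenated
#'   over subjects) restricted to, or filtered by, one parameter.
#' @param parameter which parameter to model; default the single one
#'   present.
#' @return A [MixedModelFit-class] object.
#' @export
fitAreaTimeModel <- function(longTable, parameter = NULL) {
  if (is.null(parameter)) {
    parameter <- unique(longTable$parameter)
    if (length(parameter) != 1L)
      stop("table holds several parameters; pick one")
  }
  d <- longTable[longTable$parameter == parameter, ]
  if (length(unique(d$subject_id)) < 2L) stop("need at least 2 subjects")
  if (length(unique(d$area)) < 2L) stop("need at least 2 areas")
  if (length(unique(d$timepoint)) != 2L) stop("need both timepoints")
  d$area <- factor(d$area, levels = intersect(c(.AREAS, "NAWM"),
                                              unique(d$area)))
  d$timepoint <- factor(d$timepoint, levels = c("T0", "T1"))
  d$subject <- factor(d$subject_id)
  d$series <- interaction(d$subject_id, d$unit, d$area, drop = TRUE)

  fit <- suppressMessages(lmerTest::lmer(
    log_value ~ area * timepoint + (1 | subject) + (1 | series),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  singular <- lme4::isSingular(fit)
  ddf <- if (requireNamespace("pbkrtest", quietly = TRUE))
    "Kenward-Roger" else "Satterthwaite"
  av <- suppressWarnings(as.data.frame(stats::anova(fit, type = 3,
                                                    ddf = ddf)))
  new("MixedModelFit", model = fit, anova = av, dfMethod = ddf,
      parameter = parameter, singular = singular)
}

#' Tukey-adjusted pairwise area contrasts
#'
#' All pairwise comparisons between areas within each timepoint (6
#' contrasts for 4 areas), adjusted with Tukey's studentized-range
#' procedure on the estimated marginal means of the mixed model.
#'
#' @param fit a [MixedModelFit-class] from [fitAreaTimeModel()].
#' @return data.frame with columns `contrast`, `timepoint`, `estimate`,
#'   `SE`, `df`, `t_ratio`, `p_adj`.
#' @export
pairwiseAreaContrasts <- function(fit) {
  stopifnot(is(fit, "MixedModelFit"))
  mode <- if (fit@dfMethod == "Kenward-Roger") "kenward-roger"
          else "satterthwaite"
  em <- emmeans::emmeans(fit@model, ~ area | timepoint,
                         lmer.df = mode)
  pw <- summary(emmeans::contrast(em, method = "pairwise",
                                  adjust = "tukey"))
  data.frame(contrast = pw$contrast, timepoint = pw$timepoint,
             estimate = pw$estimate, SE = pw$SE, df = pw$df,
             t_ratio = pw$t.ratio, p_adj = pw$p.value,
             stringsAsFactors = FALSE)
}
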